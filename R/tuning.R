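#' Zero-solution penalty threshold (lambda-max)
#'
#' For a given L1 mixing proportion `alpha`, returns
#' \deqn{\lambda_0 = \frac{\|\sum_i y_i x_i\|_\infty}{2 \alpha n},}
#' the smallest total penalty level at which the all-zero coefficient
#' vector satisfies the zero-subgradient condition of the objective (with
#' `lambda1 = (1 - alpha) * lambda`, `lambda2 = alpha * lambda`).  Fits at
#' `lambda >= lambda_0` return exactly zero; the tuning grids anchor
#' their lambda paths here.
#'
#' @param data a [labeled_image_dataset()].
#' @param alpha L1 mixing proportion in (0, 1].
#' @return A single nonnegative number.
#' @examples
#' d <- labeled_image_dataset(matrix(c(1, 0, 0, 0, 0, 2, 0, 0), 2, 4),
#'                            c(1, -1), image_shape(2, 2))
#' lambda_max(d, 0.5)  # 1
#' @export
lambda_max <- function(data, alpha) {
  stopifnot(inherits(data, "labeled_image_dataset"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(data$X)
  max(abs(colSums(data$X * data$y))) / (2 * alpha * n)
}

new_tuning_grid <- function(alphas, lambdas_per_alpha, provenance) {
  stopifnot(length(alphas) == length(lambdas_per_alpha),
            all(alphas > 0), all(alphas <= 1))
  for (l in lambdas_per_alpha) stopifnot(all(l > 0))
  structure(list(alphas = alphas,
                 lambdas_per_alpha = lambdas_per_alpha,
                 provenance = provenance),
            class = "tuning_grid")
}

#' @exportS3Method base::print
print.tuning_grid <- function(x, ...) {
  cat("<tuning_grid> (", x$provenance, ") ", length(x$alphas),
      " alpha values x ", length(x$lambdas_per_alpha[[1L]]),
      " lambda values per alpha\n", sep = "")
  invisible(x)
}

#' Default tuning grid
#'
#' The full grid used in the simulation studies: `alpha = 0.02 * kappa`
#' for `kappa = 1..50`, and per alpha the lambda path
#' `0.96^nu * lambda_0(alpha)` for `nu = 0..160` with the fixed small
#' value 0.001 appended — 162 lambda values, sorted descending so paths
#' can be traversed with warm starts.
#'
#' @param data a [labeled_image_dataset()] (used for the
#'   [lambda_max()] anchors).
#' @return A `tuning_grid`.
#' @export
default_grid <- function(data) {
  alphas <- 0.02 * (1:50)
  lams <- lapply(alphas, function(a) {
    c(0.96^(0:160) * lambda_max(data, a), 0.001)
  })
  lams <- lapply(lams, function(l) sort(l, decreasing = TRUE))
  new_tuning_grid(alphas, lams, "paper-default")
}

#' Reduced tuning grid
#'
#' A desk-scale grid for replicated studies: by default 4 alpha values
#' and per alpha 40 lambda values (39 geometrically spaced between
#' `lambda_0(alpha)` and `0.96^160 * lambda_0(alpha)`, plus 0.001),
#' descending.
#'
#' @inheritParams default_grid
#' @param alphas alpha values in (0, 1].
#' @param n_lambda number of lambda values per alpha (including the
#'   appended 0.001).
#' @return A `tuning_grid`.
#' @export
reduced_grid <- function(data, alphas = c(0.2, 0.5, 0.8, 1.0),
                         n_lambda = 40L) {
  stopifnot(n_lambda >= 2L)
  lams <- lapply(alphas, function(a) {
    l0 <- lambda_max(data, a)
    if (l0 <= 0) l0 <- 1  # degenerate balanced data: any path works
    path <- l0 * 0.96^seq(0, 160, length.out = n_lambda - 1L)
    sort(c(path, 0.001), decreasing = TRUE)
  })
  new_tuning_grid(alphas, lams, "reduced")
}

#' Custom tuning grid
#'
#' @param alphas alpha values in (0, 1].
#' @param lambdas either a numeric vector of lambda values shared by all
#'   alphas, or a list with one numeric vector per alpha.
#' @return A `tuning_grid` with provenance `"custom"`.
#' @export
tuning_grid <- function(alphas, lambdas) {
  if (!is.list(lambdas)) lambdas <- rep(list(lambdas), length(alphas))
  lambdas <- lapply(lambdas, function(l) sort(l, decreasing = TRUE))
  new_tuning_grid(alphas, lambdas, "custom")
}

# Tie-break for the argmin of a PE table: smallest PE, then larger
# lambda, then larger alpha (more regularization, sparser model).
select_best_row <- function(pe_table) {
  o <- order(pe_table$pe, -pe_table$lambda, -pe_table$alpha)
  pe_table[o[1L], , drop = FALSE]
}

# Fit along one alpha's lambda path (descending), optionally
# warm-starting each fit from the previous solution.  Returns a list of
# fits aligned with `lambdas`.
fit_lambda_path <- function(train, alpha, lambdas, op, config,
                            warm_start = TRUE) {
  fits <- vector("list", length(lambdas))
  init <- NULL
  for (v in seq_along(lambdas)) {
    cfg <- config
    cfg$init <- if (warm_start) init else NULL
    pen <- penalty_config(alpha = alpha, lambda = lambdas[v])
    fits[[v]] <- fit_sobologit(train, pen, op, cfg)
    init <- fits[[v]]$beta_hat
  }
  fits
}

#' Select tuning parameters on a validation set
#'
#' Fits the model on `train` at every (alpha, lambda) grid point —
#' traversing each alpha's lambda path from largest to smallest with warm
#' starts — records the misclassification rate on `validation`, and
#' returns the minimizing pair (ties broken toward larger lambda, then
#' larger alpha) together with the winning fit.
#'
#' @param train,validation [labeled_image_dataset()]s with the same shape.
#' @param grid a `tuning_grid`.
#' @param config a [solver_config()].
#' @param warm_start logical; warm-start along each lambda path.
#' @return An object of class `tuning_result`: `best_alpha`,
#'   `best_lambda`, `pe_table` (data frame alpha/lambda/pe), `fit` (the
#'   selected fit on the full training data) and `mode = "validation"`.
#' @export
select_by_validation <- function(train, validation, grid,
                                 config = solver_config(),
                                 warm_start = TRUE) {
  stopifnot(inherits(train, "labeled_image_dataset"),
            inherits(grid, "tuning_grid"))
  if (!inherits(validation, "labeled_image_dataset") ||
      nrow(validation$X) == 0L) {
    stop("`validation` must be a nonempty labeled_image_dataset",
         call. = FALSE)
  }
  if (train$shape$p != validation$shape$p ||
      train$shape$q != validation$shape$q) {
    stop("train and validation shapes differ", call. = FALSE)
  }
  op <- build_difference_operator(train$shape)

  rows <- list()
  best_fit_per_point <- list()
  for (a in seq_along(grid$alphas)) {
    alpha <- grid$alphas[a]
    lambdas <- grid$lambdas_per_alpha[[a]]
    fits <- fit_lambda_path(train, alpha, lambdas, op, config, warm_start)
    pe <- vapply(fits, function(f) {
      prediction_error(f$beta_hat, validation)
    }, numeric(1))
    rows[[a]] <- data.frame(alpha = alpha, lambda = lambdas, pe = pe)
    best_fit_per_point[[a]] <- fits
  }
  pe_table <- do.call(rbind, rows)
  rownames(pe_table) <- NULL
  best <- select_best_row(pe_table)
  a_idx <- match(best$alpha, grid$alphas)
  l_idx <- match(best$lambda, grid$lambdas_per_alpha[[a_idx]])
  structure(list(best_alpha = best$alpha,
                 best_lambda = best$lambda,
                 pe_table = pe_table,
                 fit = best_fit_per_point[[a_idx]][[l_idx]],
                 mode = "validation"),
            class = "tuning_result")
}

#' @exportS3Method base::print
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> (", x$mode, ") best alpha = ", x$best_alpha,
      ", best lambda = ", signif(x$best_lambda, 6),
      ", PE = ", signif(min(x$pe_table$pe), 4), "\n", sep = "")
  invisible(x)
}

# Stratified fold assignment: a random permutation within each label
# class dealt round-robin into M folds, so every fold keeps the class
# balance.  Reproducible from `seed`.
make_folds <- function(y, M, seed, stratify = TRUE) {
  n <- length(y)
  folds <- integer(n)
  with_seed(seed, {
    if (stratify) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(M), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(M), n))
    }
  })
  folds
}

#' M-fold cross-validated tuning
#'
#' Splits the data into `M` folds (stratified by label by default,
#' reproducibly from `seed`), computes for every grid point the
#' cross-validation prediction error
#' \eqn{PE^{(cv)} = M^{-1} \sum_m PE^{(m)}} — the mean over folds of the
#' misclassification rate on the held-out fold of the model fit on the
#' rest — and refits the minimizing pair on the full data.
#'
#' @param data a [labeled_image_dataset()].
#' @param M number of folds, between 2 and n.
#' @param grid a `tuning_grid`.
#' @param config a [solver_config()].
#' @param seed integer seed controlling the fold assignment.
#' @param stratify keep class balance within folds (default TRUE).
#' @param warm_start logical; warm-start along each lambda path.
#' @return A `tuning_result` with `mode = "cv"`; `pe_table` carries the
#'   mean PE and one `pe_fold_m` column per fold, and `folds` records the
#'   fold assignment.
#' @export
cross_validate <- function(data, M, grid, config = solver_config(),
                           seed = 1L, stratify = TRUE, warm_start = TRUE) {
  stopifnot(inherits(data, "labeled_image_dataset"),
            inherits(grid, "tuning_grid"))
  n <- nrow(data$X)
  if (M < 2 || M != as.integer(M)) {
    stop("`M` must be an integer >= 2", call. = FALSE)
  }
  if (M > n) stop("`M` cannot exceed the number of observations",
                  call. = FALSE)
  folds <- make_folds(data$y, M, seed, stratify)
  op <- build_difference_operator(data$shape)

  n_points <- sum(vapply(grid$lambdas_per_alpha, length, integer(1)))
  fold_pe <- matrix(NA_real_, n_points, M)
  for (m in seq_len(M)) {
    hold <- folds == m
    train_m <- labeled_image_dataset(data$X[!hold, , drop = FALSE],
                                     data$y[!hold], data$shape)
    valid_m <- labeled_image_dataset(data$X[hold, , drop = FALSE],
                                     data$y[hold], data$shape)
    r <- 0L
    for (a in seq_along(grid$alphas)) {
      lambdas <- grid$lambdas_per_alpha[[a]]
      fits <- fit_lambda_path(train_m, grid$alphas[a], lambdas, op,
                              config, warm_start)
      fold_pe[r + seq_along(lambdas), m] <-
        vapply(fits, function(f) prediction_error(f$beta_hat, valid_m),
               numeric(1))
      r <- r + length(lambdas)
    }
  }
  pe_table <- do.call(rbind, lapply(seq_along(grid$alphas), function(a) {
    data.frame(alpha = grid$alphas[a],
               lambda = grid$lambdas_per_alpha[[a]])
  }))
  pe_table$pe <- rowMeans(fold_pe)
  colnames(fold_pe) <- paste0("pe_fold_", seq_len(M))
  pe_table <- cbind(pe_table, as.data.frame(fold_pe))
  rownames(pe_table) <- NULL

  best <- select_best_row(pe_table)
  refit <- fit_sobologit(
    data, penalty_config(alpha = best$alpha, lambda = best$lambda),
    op, config)
  structure(list(best_alpha = best$alpha,
                 best_lambda = best$lambda,
                 pe_table = pe_table,
                 fit = refit,
                 folds = folds,
                 mode = "cv"),
            class = "tuning_result")
}

#' Write a tuning report
#'
#' Stores the PE table as `<prefix>_pe.csv` and the selected pair (plus
#' mode) as `<prefix>_selected.json`.
#'
#' @param result a `tuning_result`.
#' @param prefix output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_tuning_report <- function(result, prefix) {
  stopifnot(inherits(result, "tuning_result"))
  utils::write.csv(result$pe_table, paste0(prefix, "_pe.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(mode = result$mode, best_alpha = result$best_alpha,
         best_lambda = result$best_lambda,
         best_pe = min(result$pe_table$pe)),
    paste0(prefix, "_selected.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
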