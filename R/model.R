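#' Labeled image dataset
#'
#' Bundles an n x pq design matrix of vectorized image covariates with
#' class labels in \{-1, +1\} and the image shape.  Labels coded \{0, 1\}
#' are remapped to \{-1, +1\} with a warning (0 -> -1).
#'
#' The model has no intercept: the log-odds of the positive class is the
#' inner product of the image covariate with the coefficient image,
#' \eqn{\log(P_i / (1 - P_i)) = \langle X_i, B \rangle}.
#'
#' @param X numeric matrix, one vectorized image per row (column-major
#'   pixel order, see [vec_image()]).
#' @param y numeric vector of labels, entries in \{-1, +1\} (or \{0, 1\}).
#' @param shape the [image_shape()] of each image; `ncol(X)` must equal
#'   `p * q`.
#' @return An object of class `labeled_image_dataset`: a list with
#'   elements `X`, `y`, `shape`.
#' @export
labeled_image_dataset <- function(X, y, shape) {
  shape <- as_image_shape(shape)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("`X` contains non-finite values", call. = FALSE)
  if (ncol(X) != shape$p * shape$q) {
    stop("ncol(X) = ", ncol(X), " does not equal p*q = ",
         shape$p * shape$q, call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (all(y %in% c(0, 1)) && any(y == 0)) {
    warning("labels coded {0, 1}; remapping 0 -> -1", call. = FALSE)
    y <- ifelse(y == 0, -1, 1)
  }
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be -1 or +1", call. = FALSE)
  }
  structure(list(X = X, y = y, shape = shape),
            class = "labeled_image_dataset")
}

#' @exportS3Method base::print
print.labeled_image_dataset <- function(x, ...) {
  cat("<labeled_image_dataset> n = ", nrow(x$X), ", images ",
      x$shape$p, " x ", x$shape$q,
      ", +1 fraction = ", round(mean(x$y == 1), 3), "\n", sep = "")
  invisible(x)
}

#' Penalty configuration
#'
#' The objective carries two penalties: `lambda1` weights the Sobolev
#' quadratic form (spatial smoothness) and `lambda2` the L1 norm
#' (pixel selection).  The equivalent path parameterization used for
#' tuning is `lambda = lambda1 + lambda2`, `alpha = lambda2 / lambda`,
#' so `lambda1 = (1 - alpha) * lambda` and `lambda2 = alpha * lambda`.
#' Supply either pair; if both are supplied they must agree.
#'
#' @param lambda1 nonnegative Sobolev penalty weight.
#' @param lambda2 nonnegative L1 penalty weight.
#' @param alpha L1 mixing proportion in (0, 1].
#' @param lambda total penalty level, nonnegative.
#' @return An object of class `penalty_config` with fields `lambda1`,
#'   `lambda2`, `alpha`, `lambda`.
#' @examples
#' penalty_config(alpha = 0.5, lambda = 0.2)   # lambda1 = lambda2 = 0.1
#' @export
penalty_config <- function(lambda1 = NULL, lambda2 = NULL,
                           alpha = NULL, lambda = NULL) {
  have_direct <- !is.null(lambda1) && !is.null(lambda2)
  have_path <- !is.null(alpha) && !is.null(lambda)
  if (!have_direct && !have_path) {
    stop("supply either (lambda1, lambda2) or (alpha, lambda)",
         call. = FALSE)
  }
  if (have_path) {
    if (alpha <= 0 || alpha > 1) {
      stop("`alpha` must lie in (0, 1]", call. = FALSE)
    }
    if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
    l1 <- (1 - alpha) * lambda
    l2 <- alpha * lambda
    if (have_direct &&
        (abs(l1 - lambda1) > 1e-10 * (1 + abs(l1)) ||
         abs(l2 - lambda2) > 1e-10 * (1 + abs(l2)))) {
      stop("(lambda1, lambda2) and (alpha, lambda) are inconsistent",
           call. = FALSE)
    }
    lambda1 <- l1
    lambda2 <- l2
  } else {
    if (lambda1 < 0 || lambda2 < 0) {
      stop("penalty weights must be nonnegative", call. = FALSE)
    }
    lambda <- lambda1 + lambda2
    alpha <- if (lambda > 0) lambda2 / lambda else NA_real_
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 alpha = alpha, lambda = lambda),
            class = "penalty_config")
}

#' @exportS3Method base::print
print.penalty_config <- function(x, ...) {
  cat("<penalty_config> lambda1 (Sobolev) = ", signif(x$lambda1, 6),
      ", lambda2 (L1) = ", signif(x$lambda2, 6),
      if (!is.na(x$alpha)) paste0("  [alpha = ", signif(x$alpha, 6),
                                  ", lambda = ", signif(x$lambda, 6), "]"),
      "\n", sep = "")
  invisible(x)
}

# Stable softplus: log(1 + exp(z)) without overflow.
softplus <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

check_beta_dims <- function(beta, data) {
  if (length(beta) != ncol(data$X)) {
    stop("length of `beta` (", length(beta),
         ") does not match ncol(X) (", ncol(data$X), ")", call. = FALSE)
  }
}

#' Probability of the observed label
#'
#' For each observation returns
#' \eqn{p_i = 1 / (1 + \exp(-y_i \, x_i^T \beta))}, the model probability
#' of the label actually observed.  These are the weights the
#' coordinate-descent updates are built from.
#'
#' @param beta numeric coefficient vector of length p*q.
#' @param data a [labeled_image_dataset()].
#' @return Numeric vector of length n with entries in (0, 1).
#' @export
observed_label_probability <- function(beta, data) {
  stopifnot(inherits(data, "labeled_image_dataset"))
  check_beta_dims(beta, data)
  stats::plogis(data$y * drop(data$X %*% beta))
}

#' Empirical logistic risk
#'
#' The average logistic loss
#' \eqn{n^{-1} \sum_i \log(1 + \exp(-y_i \, x_i^T \beta))}, computed with
#' overflow-safe softplus semantics so it stays finite for any finite
#' inputs.
#'
#' @inheritParams observed_label_probability
#' @return A single nonnegative number; equals `log(2)` at `beta = 0`.
#' @export
empirical_risk <- function(beta, data) {
  stopifnot(inherits(data, "labeled_image_dataset"))
  check_beta_dims(beta, data)
  mean(softplus(-data$y * drop(data$X %*% beta)))
}

#' Penalized objective
#'
#' The criterion minimized by the solver:
#' \deqn{Q(\beta) = n^{-1}\sum_i \log(1 + e^{-y_i x_i^T \beta})
#'   + \lambda_1 \beta^T K \beta + \lambda_2 \|\beta\|_1.}
#'
#' @inheritParams observed_label_probability
#' @param penalty a [penalty_config()].
#' @param op a [build_difference_operator()] matching the data's shape.
#' @return A single nonnegative number.
#' @export
objective <- function(beta, data, penalty, op) {
  stopifnot(inherits(penalty, "penalty_config"))
  empirical_risk(beta, data) +
    penalty$lambda1 * quadratic_penalty(beta, op) +
    penalty$lambda2 * sum(abs(beta))
}

#' Classify new images
#'
#' Computes class probabilities \eqn{P(y = +1 \mid x) =
#' 1/(1 + e^{-x^T \beta})} and labels.  The decision rule predicts +1
#' when the linear predictor is positive; a linear predictor of exactly 0
#' maps to +1 by convention (deterministic tie-break).
#'
#' @param beta numeric coefficient vector of length p*q.
#' @param X numeric m x pq matrix of vectorized images.
#' @return A list with `prob` (length-m vector of P(y = +1 | x)),
#'   `label` (length-m vector in \{-1, +1\}) and `linear_predictor`.
#' @export
predict_labels <- function(beta, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) {
    stop("ncol(X) does not match length(beta)", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  list(prob = stats::plogis(eta),
       label = ifelse(eta >= 0, 1, -1),
       linear_predictor = eta)
}

#' Read / write a labeled image dataset as delimited text
#'
#' `write_dataset` stores the design matrix as `<prefix>_X.csv` (one
#' vectorized image per row, no header) and the labels as
#' `<prefix>_y.csv`; a JSON sidecar `<prefix>_meta.json` records the
#' image shape and the column-major vectorization convention.
#' `read_dataset` reads the triple back.
#'
#' @param data a [labeled_image_dataset()].
#' @param prefix file path prefix (directory must exist).
#' @return `write_dataset` invisibly returns `prefix`; `read_dataset`
#'   returns a [labeled_image_dataset()].
#' @export
write_dataset <- function(data, prefix) {
  stopifnot(inherits(data, "labeled_image_dataset"))
  utils::write.table(data$X, paste0(prefix, "_X.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data$y, paste0(prefix, "_y.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(p = data$shape$p, q = data$shape$q,
         vectorization = "column-major: pixel (j,k) -> index p*(k-1)+j"),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  X <- as.matrix(utils::read.table(paste0(prefix, "_X.csv"), sep = ","))
  dimnames(X) <- NULL
  y <- utils::read.table(paste0(prefix, "_y.csv"), sep = ",")[[1L]]
  labeled_image_dataset(X, y, image_shape(meta$p, meta$q))
}

#' Write a coefficient image to CSV
#'
#' Stores the p x q matrix as CSV (no header) plus a JSON sidecar with
#' the shape and vectorization convention; the flat vector form can be
#' recovered with [vec_image()].
#'
#' @param B a p x q coefficient image matrix.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return Invisibly, `path`.
#' @export
write_coefficient_image <- function(B, path) {
  stopifnot(is.matrix(B))
  utils::write.table(B, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(p = nrow(B), q = ncol(B),
         vectorization = "column-major: pixel (j,k) -> index p*(k-1)+j"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_coefficient_image
#' @export
read_coefficient_image <- function(path) {
  B <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(B) <- NULL
  B
}
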