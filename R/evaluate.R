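#' Prediction error (misclassification rate)
#'
#' The fraction of held-out labels that differ from the classifier's
#' predictions (accuracy = 1 - PE).  Uses the [predict_labels()] decision
#' rule, so a zero linear predictor counts as a +1 prediction.
#'
#' @param beta coefficient vector of length p*q.
#' @param test a nonempty [labeled_image_dataset()].
#' @return A number in \[0, 1\].
#' @export
prediction_error <- function(beta, test) {
  stopifnot(inherits(test, "labeled_image_dataset"))
  if (nrow(test$X) == 0L) stop("empty test set", call. = FALSE)
  pred <- predict_labels(beta, test$X)$label
  mean(pred != test$y)
}

#' Estimation error
#'
#' The squared Frobenius distance between an estimated and the true
#' coefficient image, \eqn{\sum_{j,k} (\hat b_{jk} - b^0_{jk})^2}, for a
#' single replicate; the study harness averages it across replicates.
#' Set `squared = FALSE` for the unsquared Frobenius norm.
#'
#' @param B_hat estimated coefficient image (matrix, or vector of length
#'   p*q matching `B0`).
#' @param B0 true coefficient image (matrix).
#' @param squared report the squared norm (default TRUE).
#' @return A single nonnegative number.
#' @export
estimation_error <- function(B_hat, B0, squared = TRUE) {
  if (!is.matrix(B_hat)) B_hat <- matrix(B_hat, nrow(B0), ncol(B0))
  if (!identical(dim(B_hat), dim(B0))) {
    stop("`B_hat` and `B0` have different shapes", call. = FALSE)
  }
  ss <- sum((B_hat - B0)^2)
  if (squared) ss else sqrt(ss)
}

#' Replicated simulation study
#'
#' Runs the full study protocol `n_replicates` times: generate a
#' train / validation / test triple from `config` (with a per-replicate
#' seed derived from `seed`), tune each method on the validation set over
#' the grid, and score the selected fit's prediction error on the test
#' set and estimation error against the true image.  `lg_sob` tunes over
#' the full (alpha, lambda) grid; `lg_l1` is the pure-L1 special case,
#' the same solver with the grid restricted to `alpha = 1`
#' (`lambda1 = 0`).
#'
#' @param config a [simulation_config()]; its `seed` is overridden per
#'   replicate.
#' @param methods subset of `c("lg_sob", "lg_l1")`.
#' @param n_replicates number of independent replicates.
#' @param seed master seed for the study.
#' @param grid `"reduced"` (default, see [reduced_grid()]),
#'   `"default"` (the full grid, [default_grid()]), or a
#'   `tuning_grid`.
#' @param config_solver a [solver_config()]; the default uses
#'   path-fitting tolerances (relative objective change 1e-7, at most
#'   250 sweeps per grid point).
#' @return An object of class `study_report`: `summary` (one row per
#'   method: mean PE, mean EE), `records` (one row per replicate x
#'   method), `n_replicates`, `config`.
#' @export
run_simulation_study <- function(config,
                                 methods = c("lg_sob", "lg_l1"),
                                 n_replicates = 10L,
                                 seed = 1L,
                                 grid = "reduced",
                                 config_solver = solver_config(
                                   tol_objective = 1e-7,
                                   tol_kkt = 1e-2,
                                   max_sweeps = 250L)) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 1)
  methods <- match.arg(methods, c("lg_sob", "lg_l1"), several.ok = TRUE)
  rep_seeds <- derive_seeds(seed, n_replicates)

  records <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    sim <- make_example_dataset(cfg)
    for (method in methods) {
      g <- if (inherits(grid, "tuning_grid")) {
        grid
      } else if (identical(grid, "default")) {
        default_grid(sim$train)
      } else {
        reduced_grid(sim$train)
      }
      if (method == "lg_l1") {
        keep <- which(g$alphas == 1)
        if (length(keep) == 0L) {
          # ensure a pure-L1 path exists even on grids without alpha = 1
          g <- tuning_grid(1, g$lambdas_per_alpha[[length(g$alphas)]])
        } else {
          g <- new_tuning_grid(g$alphas[keep],
                               g$lambdas_per_alpha[keep], g$provenance)
        }
      }
      tuned <- select_by_validation(sim$train, sim$validation, g,
                                    config_solver)
      records[[length(records) + 1L]] <- data.frame(
        replicate = r,
        method = method,
        alpha = tuned$best_alpha,
        lambda = tuned$best_lambda,
        pe = prediction_error(tuned$fit$beta_hat, sim$test),
        ee = estimation_error(tuned$fit$B_hat, sim$B0))
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  summary <- do.call(rbind, lapply(unique(records$method), function(mth) {
    rr <- records[records$method == mth, , drop = FALSE]
    data.frame(method = mth,
               mean_pe = mean(rr$pe),
               mean_ee = mean(rr$ee))
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, records = records,
                 n_replicates = n_replicates, config = config,
                 seed = seed),
            class = "study_report")
}

#' @exportS3Method base::print
print.study_report <- function(x, ...) {
  cat("<study_report> ", x$n_replicates, " replicates, ",
      x$config$shape$p, " x ", x$config$shape$q, " images (",
      x$config$design, " design, ", x$config$coefficient_kind,
      " truth), n_train = ", x$config$n_train, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a study report
#'
#' Writes the per-method summary as `<prefix>_summary.csv`, the
#' per-replicate records as `<prefix>_records.csv` and a JSON echo of the
#' configuration.
#'
#' @param report a `study_report`.
#' @param prefix output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_study_report <- function(report, prefix) {
  stopifnot(inherits(report, "study_report"))
  utils::write.csv(report$summary, paste0(prefix, "_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$records, paste0(prefix, "_records.csv"),
                   row.names = FALSE)
  cfg <- report$config
  jsonlite::write_json(
    list(shape = c(cfg$shape$p, cfg$shape$q), n_train = cfg$n_train,
         n_validation = cfg$n_validation, n_test = cfg$n_test,
         design = cfg$design, coefficient_kind = cfg$coefficient_kind,
         n_replicates = report$n_replicates, seed = report$seed),
    paste0(prefix, "_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read USPS-style digit data
#'
#' Parses the plain-text handwritten-digit format in which each line is a
#' digit label followed by 256 grayscale values (one 16 x 16 image per
#' line).  No download is performed; users supply the file.  Optionally
#' restricts to two digits and recodes them as -1 / +1 for binary
#' classification.
#'
#' @param path path to the text file.
#' @param digits optional length-2 vector; rows with other labels are
#'   dropped, the first digit is coded -1 and the second +1.
#' @return A [labeled_image_dataset()] (with `digits`) or a list
#'   `list(X, digit)` when `digits` is `NULL`.
#' @export
read_usps_digits <- function(path, digits = NULL) {
  raw <- utils::read.table(path)
  lab <- raw[[1L]]
  X <- as.matrix(raw[, -1L, drop = FALSE])
  dimnames(X) <- NULL
  if (ncol(X) != 256L) {
    stop("expected 256 pixel values per line", call. = FALSE)
  }
  if (is.null(digits)) return(list(X = X, digit = lab))
  stopifnot(length(digits) == 2L)
  keep <- lab %in% digits
  y <- ifelse(lab[keep] == digits[2L], 1, -1)
  labeled_image_dataset(X[keep, , drop = FALSE], y, image_shape(16, 16))
}
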