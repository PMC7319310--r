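#' Soft-thresholding operator
#'
#' The proximal map of the L1 norm, `sign(z) * pmax(abs(z) - t, 0)`.
#' Every coordinate-descent update is a soft-threshold of a Newton-style
#' step.
#'
#' @param z numeric vector.
#' @param t nonnegative threshold.
#' @return Numeric vector of the same length as `z`.
#' @examples
#' soft_threshold(c(0.5, -0.1, -0.7), 0.2)  # 0.3, 0, -0.5
#' @export
soft_threshold <- function(z, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single nonnegative number", call. = FALSE)
  }
  sign(z) * pmax(abs(z) - t, 0)
}

#' Solver configuration
#'
#' @param tol_objective relative objective-change threshold per sweep at
#'   which the sweep loop stops.
#' @param tol_kkt subgradient-residual threshold used for the `converged`
#'   flag (the residual itself is always reported).
#' @param max_sweeps cap on full coordinate sweeps.
#' @param init optional initial coefficient vector (default all zeros;
#'   used for warm starts along regularization paths).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(tol_objective = 1e-8, tol_kkt = 1e-6,
                          max_sweeps = 1000L, init = NULL) {
  stopifnot(tol_objective > 0, tol_kkt > 0, max_sweeps >= 1)
  structure(list(tol_objective = tol_objective, tol_kkt = tol_kkt,
                 max_sweeps = as.integer(max_sweeps), init = init),
            class = "solver_config")
}

#' KKT subgradient residual
#'
#' Distance from 0 to the coordinatewise subdifferential of the penalized
#' objective: for nonzero coordinates
#' `abs(grad_smooth_j + lambda2 * sign(beta_j))`, for zero coordinates
#' `pmax(abs(grad_smooth_j) - lambda2, 0)`; the maximum over coordinates
#' is returned.  Zero certifies global optimality of the convex
#' objective.
#'
#' @inheritParams objective
#' @return A single nonnegative number.
#' @export
kkt_residual <- function(beta, data, penalty, op) {
  stopifnot(inherits(data, "labeled_image_dataset"),
            inherits(penalty, "penalty_config"),
            inherits(op, "difference_operator"))
  check_beta_dims(beta, data)
  n <- nrow(data$X)
  p <- observed_label_probability(beta, data)
  grad <- drop(crossprod(data$X, (p - 1) * data$y)) / n +
    2 * penalty$lambda1 * as.numeric(op$K %*% beta)
  r <- ifelse(beta != 0,
              abs(grad + penalty$lambda2 * sign(beta)),
              pmax(abs(grad) - penalty$lambda2, 0))
  max(r)
}

#' Single coordinate-descent update
#'
#' The closed-form update for one coordinate with all others fixed.  With
#' `g_j` the coordinate gradient of the smooth part (likelihood plus
#' Sobolev quadratic) and `h_j` its curvature,
#' the update is `soft_threshold(beta_j - g_j / h_j, lambda2 / h_j)`,
#' which minimizes the one-coordinate second-order surrogate of the
#' objective.  Exposed mainly for inspection and testing; [fit_sobologit()]
#' runs the full cyclic algorithm in compiled code.
#'
#' @param j coordinate (pixel) index in 1..pq.
#' @inheritParams objective
#' @param beta current coefficient vector.
#' @return The updated value of `beta[j]` (a single number).
#' @export
coordinate_update <- function(j, beta, data, penalty, op) {
  stopifnot(inherits(data, "labeled_image_dataset"))
  check_beta_dims(beta, data)
  n <- nrow(data$X)
  p <- observed_label_probability(beta, data)
  xj <- data$X[, j]
  g <- sum((p - 1) * data$y * xj) / n +
    2 * penalty$lambda1 * sum(op$K[j, ] * beta)
  h <- sum(p * (1 - p) * xj^2) / n +
    2 * penalty$lambda1 * op$K[j, j]
  if (h < 1e-12) {
    if (g == 0) return(0)
    h <- 1e-12
  }
  soft_threshold(beta[j] - g / h, penalty$lambda2 / h)
}

#' Fit the L1 + Sobolev penalized logistic regression
#'
#' Minimizes
#' \deqn{Q(\beta) = n^{-1}\sum_i \log(1 + e^{-y_i x_i^T \beta})
#'   + \lambda_1 \beta^T K \beta + \lambda_2 \|\beta\|_1}
#' by cyclic coordinate descent with soft-thresholded Newton-style
#' updates, starting from zero (or `config$init`).  Coordinates are
#' visited in fixed ascending order; the objective is recorded after each
#' full sweep and the loop stops when its relative change falls below
#' `config$tol_objective` or `config$max_sweeps` is reached.  The
#' objective is convex with separable nonsmooth part, so coordinate
#' descent converges to the global minimizer.
#'
#' @param data a [labeled_image_dataset()].
#' @param penalty a [penalty_config()].
#' @param op optionally a precomputed [build_difference_operator()] for
#'   `data$shape`; built on the fly if `NULL`.
#' @param config a [solver_config()].
#' @return An object of class `sobologit_fit` with elements `beta_hat`,
#'   `B_hat` (the coefficient image), `objective_trajectory` (value at
#'   initialization then after each sweep), `n_sweeps`, `converged`
#'   (objective stabilized *and* KKT residual below `config$tol_kkt`),
#'   `active_set`, `kkt_residual`, plus the shape, penalty and config.
#' @examples
#' set.seed(1)
#' shape <- image_shape(3, 3)
#' X <- matrix(rnorm(50 * 9), 50, 9)
#' y <- ifelse(X[, 5] + 0.2 * rnorm(50) > 0, 1, -1)
#' d <- labeled_image_dataset(X, y, shape)
#' fit <- fit_sobologit(d, penalty_config(lambda1 = 0.01, lambda2 = 0.02))
#' fit$active_set
#' @export
fit_sobologit <- function(data, penalty, op = NULL,
                          config = solver_config()) {
  stopifnot(inherits(data, "labeled_image_dataset"),
            inherits(penalty, "penalty_config"),
            inherits(config, "solver_config"))
  if (is.null(op)) op <- build_difference_operator(data$shape)
  stopifnot(inherits(op, "difference_operator"))
  if (op$shape$p != data$shape$p || op$shape$q != data$shape$q) {
    stop("operator shape does not match data shape", call. = FALSE)
  }
  m <- ncol(data$X)
  init <- config$init
  if (is.null(init)) init <- numeric(m)
  if (length(init) != m) stop("`config$init` has wrong length", call. = FALSE)

  Kc <- methods::as(op$K, "generalMatrix")  # dgCMatrix slots for C++
  res <- cd_fit_cpp(data$X, data$y,
                    Kc@p, Kc@i, Kc@x,
                    penalty$lambda1, penalty$lambda2,
                    as.numeric(init),
                    config$tol_objective, config$max_sweeps)
  beta_hat <- res$beta
  kkt <- kkt_residual(beta_hat, data, penalty, op)
  structure(list(
    beta_hat = beta_hat,
    B_hat = unvec_image(beta_hat, data$shape),
    objective_trajectory = res$objective_trajectory,
    n_sweeps = res$n_sweeps,
    converged = isTRUE(res$converged) && kkt <= config$tol_kkt,
    active_set = which(beta_hat != 0),
    kkt_residual = kkt,
    shape = data$shape,
    penalty = penalty,
    config = config),
    class = "sobologit_fit")
}

#' @exportS3Method base::print
print.sobologit_fit <- function(x, ...) {
  traj <- x$objective_trajectory
  cat("<sobologit_fit> ", x$shape$p, " x ", x$shape$q, " coefficient image\n",
      "  lambda1 = ", signif(x$penalty$lambda1, 6),
      ", lambda2 = ", signif(x$penalty$lambda2, 6), "\n",
      "  sweeps = ", x$n_sweeps,
      ", objective = ", signif(traj[length(traj)], 8),
      ", active set = ", length(x$active_set), " / ", length(x$beta_hat), "\n",
      "  converged = ", x$converged,
      " (KKT residual ", signif(x$kkt_residual, 3), ")\n", sep = "")
  invisible(x)
}

#' Predict method for fitted models
#'
#' @param object a `sobologit_fit`.
#' @param newdata an m x pq matrix of vectorized images or a
#'   [labeled_image_dataset()].
#' @param ... unused.
#' @return See [predict_labels()].
#' @export
predict.sobologit_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_image_dataset")) newdata <- newdata$X
  predict_labels(object$beta_hat, newdata)
}

#' Serialize a fit as JSON + CSV
#'
#' Writes `<prefix>.json` (penalty, diagnostics, objective trajectory)
#' and `<prefix>_B.csv` (the coefficient image, see
#' [write_coefficient_image()]).
#'
#' @param fit a `sobologit_fit`.
#' @param prefix output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "sobologit_fit"))
  jsonlite::write_json(
    list(shape = c(fit$shape$p, fit$shape$q),
         lambda1 = fit$penalty$lambda1, lambda2 = fit$penalty$lambda2,
         n_sweeps = fit$n_sweeps, converged = fit$converged,
         kkt_residual = fit$kkt_residual,
         active_set = fit$active_set,
         objective_trajectory = fit$objective_trajectory),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  write_coefficient_image(fit$B_hat, paste0(prefix, "_B.csv"))
  invisible(prefix)
}
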