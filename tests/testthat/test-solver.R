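test_that("soft-thresholding is the L1 proximal map", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.1, 0.2), 0)
  expect_equal(soft_threshold(-0.7, 0.2), -0.5)
  expect_equal(soft_threshold(c(1, -1, 0), 0), c(1, -1, 0))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("coordinate update minimizes the one-coordinate surrogate", {
  d <- random_instance(21, n = 30, p = 2, q = 2)
  op <- build_difference_operator(d$shape)
  pen <- penalty_config(lambda1 = 0.05, lambda2 = 0.08)
  set.seed(22)
  beta <- rnorm(4, sd = 0.4)
  n <- nrow(d$X)
  for (j in 1:4) {
    # independent scalar oracle: numerically minimize the quadratic
    # surrogate Q~(b) built from the same expansion point
    p_i <- observed_label_probability(beta, d)
    xj <- d$X[, j]
    g <- sum((p_i - 1) * d$y * xj) / n + 2 * pen$lambda1 *
      sum(as.matrix(op$K)[j, ] * beta)
    h <- sum(p_i * (1 - p_i) * xj^2) / n + 2 * pen$lambda1 *
      as.matrix(op$K)[j, j]
    surrogate <- function(b) {
      g * (b - beta[j]) + 0.5 * h * (b - beta[j])^2 + pen$lambda2 * abs(b)
    }
    oracle <- optimize(surrogate, c(-10, 10), tol = 1e-12)$minimum
    # optimize() itself is only accurate to ~sqrt(eps)
    expect_equal(coordinate_update(j, beta, d, pen, op), oracle,
                 tolerance = 1e-6)
  }
})

test_that("coordinate update zeroes degenerate and over-thresholded coordinates", {
  d <- random_instance(31, n = 20, p = 2, q = 2)
  d$X[, 2] <- 0  # degenerate column
  op <- build_difference_operator(d$shape)
  pen0 <- penalty_config(lambda1 = 0, lambda2 = 0.01)
  expect_equal(coordinate_update(2, numeric(4), d, pen0, op), 0)

  # enormous lambda2: threshold exceeds any step
  pen_big <- penalty_config(lambda1 = 0.01, lambda2 = 1e6)
  set.seed(32)
  beta <- rnorm(4)
  expect_equal(coordinate_update(1, beta, d, pen_big, op), 0)
})

test_that("unpenalized fit matches glm on a well-conditioned instance", {
  set.seed(41)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4)
  beta0 <- c(1, -0.5, 0, 0.8)
  y <- ifelse(runif(n) < plogis(drop(X %*% beta0)), 1, -1)
  d <- labeled_image_dataset(X, y, image_shape(2, 2))
  fit <- fit_sobologit(d, penalty_config(lambda1 = 0, lambda2 = 0),
                       config = solver_config(tol_objective = 1e-12,
                                              max_sweeps = 5000))
  # IRLS oracle: glm without intercept on the 0/1 recoding
  g <- glm(I(y == 1) ~ X - 1, family = binomial())
  expect_equal(fit$beta_hat, unname(coef(g)), tolerance = 1e-4)
})

test_that("coordinate descent reaches the FISTA oracle optimum", {
  set.seed(51)
  cases <- expand.grid(l1 = c(0.001, 0.01, 0.1), l2 = c(0.002, 0.02, 0.2))
  for (i in seq_len(nrow(cases))) {
    d <- random_instance(100 + i, n = 35, p = 4, q = 5)
    op <- build_difference_operator(d$shape)
    pen <- penalty_config(lambda1 = cases$l1[i], lambda2 = cases$l2[i])
    fit <- fit_sobologit(d, pen, op,
                         solver_config(tol_objective = 1e-12,
                                       max_sweeps = 20000))
    oracle <- oracle_fista(d, pen, op)
    q_cd <- objective(fit$beta_hat, d, pen, op)
    expect_lte(q_cd, oracle$objective + 1e-6)
    expect_lte(fit$kkt_residual, 1e-6)
  }
})

test_that("objective trajectory is non-increasing and recorded per sweep", {
  for (s in 1:5) {
    d <- random_instance(200 + s)
    pen <- penalty_config(lambda1 = 10^runif(1, -3, 0),
                          lambda2 = 10^runif(1, -3, 0))
    fit <- fit_sobologit(d, pen)
    expect_true(all(diff(fit$objective_trajectory) <= 1e-12))
    expect_length(fit$objective_trajectory, fit$n_sweeps + 1)
    expect_equal(fit$objective_trajectory[1], log(2))
  }
})

test_that("non-convergence is reported, not thrown", {
  d <- random_instance(61)
  fit <- fit_sobologit(d, penalty_config(lambda1 = 0, lambda2 = 1e-5),
                       config = solver_config(tol_objective = 1e-15,
                                              max_sweeps = 3))
  expect_false(fit$converged)
  expect_s3_class(fit, "sobologit_fit")
  d$X[1, 1] <- NA
  expect_error(labeled_image_dataset(d$X, d$y, d$shape), "non-finite")
})

test_that("KKT residual certifies optimality and flags non-optimality", {
  d <- random_instance(71, n = 30, p = 3, q = 3)
  op <- build_difference_operator(d$shape)

  # beta = 0 with lambda2 at the subgradient bound: residual exactly 0
  bound <- max(abs(colSums(d$X * d$y))) / (2 * nrow(d$X))
  pen <- penalty_config(lambda1 = 0.01, lambda2 = bound * 1.0001)
  expect_equal(kkt_residual(numeric(9), d, pen, op), 0)

  # at an oracle solution the residual is tiny; away from it, not
  pen2 <- penalty_config(lambda1 = 0.02, lambda2 = 0.03)
  sol <- oracle_fista(d, pen2, op)
  expect_lte(kkt_residual(sol$beta, d, pen2, op), 1e-5)
  set.seed(72)
  expect_gt(kkt_residual(rnorm(9), d, pen2, op), 1e-3)
})

test_that("pure-L1 fits agree with glmnet on the shared objective", {
  skip_if_not_installed("glmnet")
  for (s in 1:4) {
    d <- random_instance(300 + s, n = 40, p = 3, q = 3)
    op <- build_difference_operator(d$shape)
    lam <- 0.05 / s
    pen <- penalty_config(lambda1 = 0, lambda2 = lam)
    fit <- fit_sobologit(d, pen, op,
                         solver_config(tol_objective = 1e-13,
                                       max_sweeps = 20000))
    gn <- glmnet::glmnet(d$X, factor(d$y), family = "binomial",
                         alpha = 1, lambda = lam, intercept = FALSE,
                         standardize = FALSE, thresh = 1e-14)
    beta_gn <- as.numeric(gn$beta)
    q_cd <- objective(fit$beta_hat, d, pen, op)
    q_gn <- objective(beta_gn, d, pen, op)
    expect_lte(abs(q_cd - q_gn), 1e-6)
  }
})

test_that("final objective is invariant to coordinate ordering", {
  d <- random_instance(81, n = 40, p = 3, q = 3)
  op <- build_difference_operator(d$shape)
  pen <- penalty_config(lambda1 = 0.02, lambda2 = 0.01)
  cfg <- solver_config(tol_objective = 1e-13, max_sweeps = 20000)
  fit <- fit_sobologit(d, pen, op, cfg)

  # permute the pixel order (columns of X, rows/cols of K) and refit:
  # same problem in disguise, so the optimum must match
  set.seed(82)
  perm <- sample(9)
  dperm <- labeled_image_dataset(d$X[, perm], d$y, d$shape)
  op_perm <- op
  op_perm$K <- op$K[perm, perm]
  op_perm$D <- op$D[, perm]
  fit2 <- fit_sobologit(dperm, pen, op_perm, cfg)
  expect_equal(objective(fit$beta_hat, d, pen, op),
               objective(fit2$beta_hat, dperm, pen, op_perm),
               tolerance = 1e-8)
  expect_equal(fit2$beta_hat[order(perm)], fit$beta_hat, tolerance = 1e-5)
})

test_that("warm starts reach the same solution as cold starts", {
  d <- random_instance(91, n = 40, p = 3, q = 3)
  op <- build_difference_operator(d$shape)
  cfg <- solver_config(tol_objective = 1e-12, max_sweeps = 10000)
  pen <- penalty_config(alpha = 0.5, lambda = 0.3 * lambda_max(d, 0.5))
  cold <- fit_sobologit(d, pen, op, cfg)
  warm_cfg <- cfg
  warm_cfg$init <- fit_sobologit(
    d, penalty_config(alpha = 0.5, lambda = 0.5 * lambda_max(d, 0.5)),
    op, cfg)$beta_hat
  warm <- fit_sobologit(d, pen, op, warm_cfg)
  expect_equal(objective(warm$beta_hat, d, pen, op),
               objective(cold$beta_hat, d, pen, op), tolerance = 1e-8)
})

test_that("fit serialization writes JSON diagnostics and the image", {
  d <- random_instance(95, n = 25, p = 3, q = 3)
  fit <- fit_sobologit(d, penalty_config(lambda1 = 0.01, lambda2 = 0.05))
  pre <- file.path(tempdir(), "fitout")
  write_fit(fit, pre)
  js <- jsonlite::read_json(paste0(pre, ".json"))
  expect_equal(js$n_sweeps, fit$n_sweeps)
  expect_equal(read_coefficient_image(paste0(pre, "_B.csv")), fit$B_hat,
               tolerance = 1e-12)
})
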