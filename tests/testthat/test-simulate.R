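test_that("binary shape images have the stated value structure", {
  shp <- image_shape(32, 32)
  # radius-0 disk: exactly one pixel
  B <- make_binary_shape_image(shp, radius = 0, center = c(16, 16))
  expect_equal(sum(B), 1)
  expect_true(all(B %in% c(0, 1)))

  # full-cover rectangle: constant image, zero Sobolev norm
  B <- make_binary_shape_image(shp, motif = "rectangle",
                               extent = c(1, 32, 1, 32))
  expect_true(all(B == 1))
  expect_equal(sobolev_norm(B), 0)

  # radius-8 disk: ones equal the brute-force lattice-point count
  B <- make_binary_shape_image(shp, radius = 8)
  cnt <- 0
  for (j in 1:32) for (k in 1:32) {
    if ((j - 16.5)^2 + (k - 16.5)^2 <= 64) cnt <- cnt + 1
  }
  expect_equal(sum(B), cnt)

  expect_error(make_binary_shape_image(image_shape(8, 8), radius = 6),
               "bounds")
  expect_error(make_binary_shape_image(shp, motif = "rectangle",
                                       extent = c(1, 40, 1, 10)), "bounds")
})

test_that("smooth images hit the requested range exactly and reproducibly", {
  shp <- image_shape(16, 16)
  expect_error(make_smooth_image(shp, c(0, 0)), "min < max")
  expect_error(make_smooth_image(shp, c(-1, -1)), "min < max")

  rng <- c(-0.0197, 0.0628)
  B1 <- make_smooth_image(shp, rng, seed = 5)
  expect_equal(min(B1), rng[1], tolerance = 1e-12)
  expect_equal(max(B1), rng[2], tolerance = 1e-12)
  expect_identical(B1, make_smooth_image(shp, rng, seed = 5))
  expect_false(identical(B1, make_smooth_image(shp, rng, seed = 6)))
})

test_that("AR design realizes the rho^|j1-j2| covariance", {
  shp <- image_shape(4, 8)   # 32 pixels
  X0 <- sample_ar_design(4000, shp, rho = 0, seed = 1)
  cors <- cor(X0)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.08)

  X <- sample_ar_design(20000, shp, rho = 0.5, seed = 2)
  m <- ncol(X)
  lag1 <- mean(sapply(1:(m - 1), function(j) cor(X[, j], X[, j + 1])))
  lag2 <- mean(sapply(1:(m - 2), function(j) cor(X[, j], X[, j + 2])))
  expect_lt(abs(lag1 - 0.5), 0.02)
  expect_lt(abs(lag2 - 0.25), 0.02)
  expect_lt(max(abs(apply(X, 2, var) - 1)), 0.05)

  # analytic 3-pixel covariance on a tiny shape, within Monte-Carlo error
  X3 <- sample_ar_design(20000, image_shape(3, 2), rho = 0.5, seed = 3)[, 1:3]
  emp <- cov(X3)
  expect_equal(emp, rbind(c(1, .5, .25), c(.5, 1, .5), c(.25, .5, 1)),
               tolerance = 0.05, ignore_attr = TRUE)

  expect_error(sample_ar_design(10, shp, rho = 1), "rho")
})

test_that("Haar basis is orthonormal and enumerated coarse to fine", {
  Phi <- haar_basis(image_shape(8, 8))
  G <- crossprod(Phi)
  expect_lt(max(abs(G - diag(64))), 1e-10)
  # constant function first
  expect_equal(Phi[, 1], rep(1 / 8, 64))
  # second function is a coarse half-split, support the whole image
  expect_equal(sum(Phi[, 2] != 0), 64)
  expect_error(haar_basis(image_shape(6, 6)), "power-of-two")
  expect_error(haar_basis(image_shape(4, 8)), "power-of-two")
})

test_that("Haar design matches its closed-form pixel covariance", {
  shp <- image_shape(8, 8)
  # single basis function: multiples of the constant image
  X1 <- sample_haar_design(50, shp, n_basis = 1, seed = 4)
  expect_equal(apply(X1, 1, function(r) max(r) - min(r)), rep(0, 50))

  Phi <- haar_basis(shp)
  L <- 64
  Sigma <- Phi %*% diag(1 / (1:L)^2) %*% t(Phi)
  X <- sample_haar_design(20000, shp, seed = 5)
  expect_lt(max(abs(cov(X) - Sigma)), 0.05)
})

test_that("labels are calibrated to the logistic curve", {
  shp <- image_shape(4, 4)
  X <- sample_ar_design(10000, shp, 0.5, seed = 6)

  # zero signal: fair coin
  y0 <- sample_labels(X, matrix(0, 4, 4), seed = 7)
  expect_lt(abs(mean(y0 == 1) - 0.5), 0.02)

  # saturated signal: all +1
  Xbig <- matrix(1, 200, 16)
  ybig <- sample_labels(Xbig, matrix(20 / 16, 4, 4), seed = 8)
  expect_true(all(ybig == 1))

  # binned calibration against the logistic curve
  B0 <- matrix(rnorm(16, sd = 0.3), 4, 4)
  X <- sample_ar_design(50000, shp, 0.5, seed = 9)
  y <- sample_labels(X, B0, seed = 10)
  eta <- drop(X %*% vec_image(B0))
  bins <- cut(eta, quantile(eta, seq(0, 1, 0.1)), include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    phat <- mean(y[sel] == 1)
    pexp <- mean(plogis(eta[sel]))
    se <- sqrt(pexp * (1 - pexp) / sum(sel))
    expect_lt(abs(phat - pexp), 3 * se + 1e-8)
  }
})

test_that("example datasets are reproducible with disjoint sub-streams", {
  cfg <- simulation_config(shape = c(8, 8), n_train = 40,
                           n_validation = 30, n_test = 20,
                           design = "ar", coefficient_kind = "binary_shape",
                           seed = 99)
  sim1 <- make_example_dataset(cfg)
  sim2 <- make_example_dataset(cfg)
  expect_identical(sim1$train$X, sim2$train$X)
  expect_identical(sim1$validation$y, sim2$validation$y)
  expect_identical(sim1$B0, sim2$B0)
  expect_equal(nrow(sim1$train$X), 40)
  expect_equal(nrow(sim1$validation$X), 30)
  expect_equal(nrow(sim1$test$X), 20)
  # different sub-streams: no shared rows between splits
  expect_false(any(duplicated(rbind(sim1$train$X, sim1$validation$X,
                                    sim1$test$X))))

  cfg2 <- cfg; cfg2$seed <- 100L
  sim3 <- make_example_dataset(cfg2)
  expect_false(identical(sim1$train$X, sim3$train$X))
  expect_false(identical(sim1$train$y, sim3$train$y) &&
                 identical(sim1$test$y, sim3$test$y))

  # haar + smooth variant
  cfg4 <- simulation_config(shape = c(8, 8), n_train = 10,
                            n_validation = 5, n_test = 5,
                            design = "haar", coefficient_kind = "smooth",
                            seed = 1)
  sim4 <- make_example_dataset(cfg4)
  expect_equal(range(sim4$B0), c(-0.0197, 0.0628), tolerance = 1e-10)
})

test_that("simulation manifest and files land on disk", {
  cfg <- simulation_config(shape = c(4, 4), n_train = 8, n_validation = 4,
                           n_test = 4, seed = 3)
  sim <- make_example_dataset(cfg)
  dir <- file.path(tempdir(), "simout")
  write_simulation(sim, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_equal(unlist(man$shape), c(4, 4))
  expect_true(length(man$checksums) >= 10)
  back <- read_dataset(file.path(dir, "train"))
  expect_equal(back$X, sim$train$X, tolerance = 1e-12)
})
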