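#' Simulation configuration
#'
#' Describes one synthetic study condition: image shape, sample sizes,
#' design-matrix process, true coefficient image and seed.  Defaults
#' mirror the reference study conditions: 32 x 32 images, validation and
#' test sets of 500, AR correlation 0.5 over the vectorized pixel index,
#' and smooth coefficient values in \[-0.0197, 0.0628\].
#'
#' @param shape image shape (default 32 x 32).
#' @param n_train training-set size (default 500).
#' @param n_validation validation-set size (default 500).
#' @param n_test test-set size (default 500).
#' @param design `"ar"` for the AR-correlated Gaussian design or
#'   `"haar"` for the Haar-wavelet spatially correlated process.
#' @param coefficient_kind `"binary_shape"` for a piecewise-constant
#'   \{0, 1\} image or `"smooth"` for a smooth-valued image.
#' @param ar_rho AR correlation parameter in (-1, 1) (default 0.5).
#' @param value_range range of the smooth coefficient image.
#' @param n_basis number of Haar basis functions (default all p*q).
#' @param motif motif of the binary coefficient image (see
#'   [make_binary_shape_image()]); default a centered disk of radius
#'   `floor(min(p, q) / 4)`.
#' @param seed master seed; all sub-streams are derived from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(shape = c(32, 32),
                              n_train = 500L,
                              n_validation = 500L,
                              n_test = 500L,
                              design = c("ar", "haar"),
                              coefficient_kind = c("binary_shape", "smooth"),
                              ar_rho = 0.5,
                              value_range = c(-0.0197, 0.0628),
                              n_basis = NULL,
                              motif = "disk",
                              seed = 1L) {
  shape <- as_image_shape(shape)
  design <- match.arg(design)
  coefficient_kind <- match.arg(coefficient_kind)
  stopifnot(n_train >= 1, n_validation >= 1, n_test >= 1,
            abs(ar_rho) < 1)
  structure(list(shape = shape, n_train = as.integer(n_train),
                 n_validation = as.integer(n_validation),
                 n_test = as.integer(n_test),
                 design = design, coefficient_kind = coefficient_kind,
                 ar_rho = ar_rho, value_range = value_range,
                 n_basis = n_basis, motif = motif,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Piecewise-constant binary coefficient image
#'
#' Generates a \{0, 1\} coefficient image whose 1-region is a single
#' 4-connected motif — a disk, a cross or an axis-aligned rectangle —
#' standing in for figure-only piecewise-constant truth images with the
#' same value structure (background 0, shape 1).
#'
#' @param shape an [image_shape()].
#' @param motif `"disk"`, `"cross"` or `"rectangle"`.
#' @param center motif center `c(row, col)` (default image center).
#' @param radius disk radius in pixels (`motif = "disk"`); radius 0
#'   gives a single pixel.
#' @param arm_length,thickness cross half-arm length and bar thickness
#'   (`motif = "cross"`).
#' @param extent rectangle `c(row1, row2, col1, col2)`
#'   (`motif = "rectangle"`).
#' @return A p x q matrix with entries in \{0, 1\}.
#' @examples
#' sum(make_binary_shape_image(image_shape(32, 32), radius = 8))
#' @export
make_binary_shape_image <- function(shape,
                                    motif = c("disk", "cross", "rectangle"),
                                    center = NULL, radius = NULL,
                                    arm_length = NULL, thickness = 1L,
                                    extent = NULL) {
  shape <- as_image_shape(shape)
  motif <- match.arg(motif)
  p <- shape$p; q <- shape$q
  if (is.null(center)) center <- c((p + 1) / 2, (q + 1) / 2)
  B <- matrix(0, p, q)
  rows <- matrix(seq_len(p), p, q)
  cols <- matrix(seq_len(q), p, q, byrow = TRUE)
  if (motif == "disk") {
    if (is.null(radius)) radius <- floor(min(p, q) / 4)
    if (radius < 0) stop("`radius` must be nonnegative", call. = FALSE)
    if (center[1] - radius < 1 || center[1] + radius > p ||
        center[2] - radius < 1 || center[2] + radius > q) {
      stop("disk exceeds image bounds", call. = FALSE)
    }
    B[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- 1
  } else if (motif == "cross") {
    if (is.null(arm_length)) arm_length <- floor(min(p, q) / 4)
    half <- (thickness - 1) / 2
    if (center[1] - arm_length < 1 || center[1] + arm_length > p ||
        center[2] - arm_length < 1 || center[2] + arm_length > q) {
      stop("cross exceeds image bounds", call. = FALSE)
    }
    vert <- abs(rows - center[1]) <= arm_length &
      abs(cols - center[2]) <= half
    horiz <- abs(cols - center[2]) <= arm_length &
      abs(rows - center[1]) <= half
    B[vert | horiz] <- 1
  } else {
    if (is.null(extent)) stop("`extent` required for rectangle motif",
                              call. = FALSE)
    if (extent[1] < 1 || extent[2] > p || extent[3] < 1 || extent[4] > q ||
        extent[1] > extent[2] || extent[3] > extent[4]) {
      stop("rectangle exceeds image bounds", call. = FALSE)
    }
    B[extent[1]:extent[2], extent[3]:extent[4]] <- 1
  }
  B
}

#' Smooth random coefficient image
#'
#' Draws a low-frequency random surface (a random combination of the
#' lowest `n_modes` cosine modes in each direction) and affinely rescales
#' it so its minimum and maximum equal the requested endpoints exactly.
#' Stands in for figure-only smooth-valued truth images with the same
#' value range.
#'
#' @param shape an [image_shape()].
#' @param value_range `c(min, max)` with `min < max`.
#' @param n_modes smoothness knob: number of cosine modes per direction
#'   (small = smoother; default 3).
#' @param seed integer seed; the image is deterministic given it.
#' @return A p x q matrix with `min(B) == value_range[1]` and
#'   `max(B) == value_range[2]`.
#' @export
make_smooth_image <- function(shape, value_range = c(-0.0197, 0.0628),
                              n_modes = 3L, seed = 1L) {
  shape <- as_image_shape(shape)
  if (length(value_range) != 2L || !all(is.finite(value_range)) ||
      value_range[1] >= value_range[2]) {
    stop("`value_range` must be c(min, max) with min < max", call. = FALSE)
  }
  p <- shape$p; q <- shape$q
  u <- (seq_len(p) - 0.5) / p
  v <- (seq_len(q) - 0.5) / q
  B <- with_seed(seed, {
    S <- matrix(0, p, q)
    for (a in 0:n_modes) {
      for (b in 0:n_modes) {
        if (a == 0 && b == 0) next
        w <- stats::rnorm(1) / (1 + a + b)   # decay damps high modes
        S <- S + w * outer(cos(pi * a * u), cos(pi * b * v))
      }
    }
    S
  })
  rng <- range(B)
  if (rng[1] == rng[2]) {
    # degenerate draw (all mode weights ~0): fall back to a linear ramp
    B <- outer(u, v, `+`)
    rng <- range(B)
  }
  value_range[1] + (B - rng[1]) / (rng[2] - rng[1]) * diff(value_range)
}

#' AR-correlated Gaussian design matrix
#'
#' Draws `n` vectorized images whose pixels are jointly Gaussian with
#' mean zero and covariance `rho^|j1 - j2|` over the *vectorized* pixel
#' index (column-major), exactly as in the reference design.  Generated
#' by the AR(1) recursion `x_1 = e_1`,
#' `x_j = rho * x_{j-1} + sqrt(1 - rho^2) * e_j`, which realizes this
#' covariance exactly in O(n * pq).
#'
#' @param n number of images.
#' @param shape an [image_shape()].
#' @param rho AR parameter, `abs(rho) < 1`.
#' @param seed integer seed.
#' @return An n x pq numeric matrix.
#' @export
sample_ar_design <- function(n, shape, rho = 0.5, seed = 1L) {
  shape <- as_image_shape(shape)
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  m <- shape$p * shape$q
  with_seed(seed, {
    E <- matrix(stats::rnorm(n * m), n, m)
    if (rho != 0 && m > 1L) {
      E[, -1L] <- E[, -1L] * sqrt(1 - rho^2)
      # recursive filter along the pixel index, one series per image row
      X <- stats::filter(t(E), rho, method = "recursive")
      t(matrix(as.numeric(X), m, n))
    } else {
      E
    }
  })
}

#' Orthonormal bivariate Haar basis
#'
#' Enumerates the 2-D multiresolution Haar basis of an N x N image
#' (N a power of two): the constant function first, then scales coarse
#' to fine; within a scale, support blocks row-major by position; within
#' a block, the three detail orientations in the fixed order horizontal,
#' vertical, diagonal.  Columns are the vectorized basis images.
#'
#' @param shape a square power-of-two [image_shape()].
#' @return A pq x pq orthonormal matrix.
#' @export
haar_basis <- function(shape) {
  shape <- as_image_shape(shape)
  p <- shape$p; q <- shape$q
  is_pow2 <- function(x) x >= 2 && bitwAnd(x, x - 1L) == 0L
  if (p != q || !is_pow2(p)) {
    stop("the Haar construction requires a square power-of-two shape",
         call. = FALSE)
  }
  N <- p
  J <- as.integer(round(log2(N)))
  Phi <- matrix(0, N * N, N * N)
  Phi[, 1L] <- 1 / N
  l <- 1L
  for (lev in 0:(J - 1L)) {
    m <- N %/% 2L^lev          # block side at this scale
    h <- m %/% 2L
    for (bu in 0:(2L^lev - 1L)) {       # block row (row-major positions)
      for (bv in 0:(2L^lev - 1L)) {
        r0 <- bu * m; c0 <- bv * m
        top <- r0 + seq_len(h); bot <- r0 + h + seq_len(h)
        left <- c0 + seq_len(h); rgt <- c0 + h + seq_len(h)
        for (orient in c("h", "v", "d")) {
          img <- matrix(0, N, N)
          s <- 1 / m
          if (orient == "h") {          # split along rows
            img[top, c(left, rgt)] <- s
            img[bot, c(left, rgt)] <- -s
          } else if (orient == "v") {   # split along columns
            img[c(top, bot), left] <- s
            img[c(top, bot), rgt] <- -s
          } else {                      # diagonal
            img[top, left] <- s; img[bot, rgt] <- s
            img[top, rgt] <- -s; img[bot, left] <- -s
          }
          l <- l + 1L
          Phi[, l] <- as.vector(img)
        }
      }
    }
  }
  Phi
}

#' Haar-wavelet spatially correlated design matrix
#'
#' Draws `n` images from the spatially correlated random process
#' \eqn{X_i = \sum_{l = 1}^{L} l^{-1} \eta_{il} \varphi_l}, with
#' `eta_il` i.i.d. standard normal and `phi_l` the orthonormal bivariate
#' Haar basis of [haar_basis()] (coarse-to-fine enumeration, so the
#' `1/l` weights damp fine-scale detail).
#'
#' @param n number of images.
#' @param shape a square power-of-two [image_shape()].
#' @param n_basis number of basis functions L (default all pq).
#' @param seed integer seed.
#' @return An n x pq numeric matrix.
#' @export
sample_haar_design <- function(n, shape, n_basis = NULL, seed = 1L) {
  shape <- as_image_shape(shape)
  Phi <- haar_basis(shape)
  m <- ncol(Phi)
  if (is.null(n_basis)) n_basis <- m
  if (n_basis < 1 || n_basis > m) {
    stop("`n_basis` must lie in 1..pq", call. = FALSE)
  }
  with_seed(seed, {
    eta <- matrix(stats::rnorm(n * n_basis), n, n_basis)
    eta <- sweep(eta, 2L, 1 / seq_len(n_basis), `*`)
    eta %*% t(Phi[, seq_len(n_basis), drop = FALSE])
  })
}

#' Sample labels from the logistic two-point distribution
#'
#' Draws independent labels with
#' \eqn{P(Y_i = +1 \mid X_i) = 1 / (1 + e^{-\langle X_i, B_0 \rangle})}.
#'
#' @param X an n x pq design matrix of vectorized images.
#' @param B0 the true coefficient image (p x q matrix) or its vectorized
#'   form.
#' @param seed integer seed.
#' @return A length-n vector with entries in \{-1, +1\}.
#' @export
sample_labels <- function(X, B0, seed = 1L) {
  beta0 <- if (is.matrix(B0)) vec_image(B0) else as.numeric(B0)
  if (ncol(X) != length(beta0)) {
    stop("ncol(X) does not match the coefficient image size", call. = FALSE)
  }
  prob <- stats::plogis(drop(X %*% beta0))
  with_seed(seed, ifelse(stats::runif(nrow(X)) < prob, 1, -1))
}

#' Generate a complete synthetic study dataset
#'
#' Draws the true coefficient image and disjoint train / validation /
#' test sets under one [simulation_config()].  All random sub-streams
#' (truth image, three designs, three label vectors) are derived
#' deterministically from `config$seed`, so the whole triple is
#' bit-reproducible.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `train`, `validation`, `test`
#'   ([labeled_image_dataset()]s), `B0` (the true coefficient image) and
#'   `config`.
#' @export
make_example_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$seed, 7L)
  shape <- config$shape

  B0 <- switch(config$coefficient_kind,
    binary_shape = make_binary_shape_image(shape, motif = config$motif),
    smooth = make_smooth_image(shape, config$value_range, seed = seeds[1L]))

  draw <- function(n, design_seed, label_seed) {
    X <- switch(config$design,
      ar = sample_ar_design(n, shape, config$ar_rho, design_seed),
      haar = sample_haar_design(n, shape, config$n_basis, design_seed))
    y <- sample_labels(X, B0, label_seed)
    labeled_image_dataset(X, y, shape)
  }
  list(train = draw(config$n_train, seeds[2L], seeds[3L]),
       validation = draw(config$n_validation, seeds[4L], seeds[5L]),
       test = draw(config$n_test, seeds[6L], seeds[7L]),
       B0 = B0,
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes the train / validation / test splits (see [write_dataset()]),
#' the true coefficient image and a JSON manifest (config, seed, and
#' per-file checksums of the written text) into a directory.
#'
#' @param sim output of [make_example_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(sim$train, file.path(dir, "train"))
  write_dataset(sim$validation, file.path(dir, "validation"))
  write_dataset(sim$test, file.path(dir, "test"))
  write_coefficient_image(sim$B0, file.path(dir, "B0.csv"))
  files <- list.files(dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  checksums <- vapply(files, function(f) {
    as.character(sum(as.integer(charToRaw(
      paste(readLines(f, warn = FALSE), collapse = "\n")))))
  }, character(1))
  cfg <- sim$config
  jsonlite::write_json(
    list(shape = c(cfg$shape$p, cfg$shape$q),
         n_train = cfg$n_train, n_validation = cfg$n_validation,
         n_test = cfg$n_test, design = cfg$design,
         coefficient_kind = cfg$coefficient_kind,
         ar_rho = cfg$ar_rho, value_range = cfg$value_range,
         motif = cfg$motif, seed = cfg$seed,
         checksums = as.list(stats::setNames(checksums, basename(files)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
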