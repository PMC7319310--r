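#' Image shape
#'
#' A validated pair of pixel dimensions (p rows, q columns).  Both must be
#' at least 2: the adjacent-pixel difference operator needs at least one
#' difference in each direction, and a 1-pixel-wide image would silently
#' degenerate to a one-dimensional fused penalty, which this package does
#' not define.
#'
#' @param p integer number of pixel rows.
#' @param q integer number of pixel columns.
#' @return An object of class `image_shape`, a list with elements `p` and `q`.
#' @examples
#' image_shape(16, 16)
#' @export
image_shape <- function(p, q) {
  if (length(p) != 1L || length(q) != 1L ||
      !is.finite(p) || !is.finite(q) ||
      p != as.integer(p) || q != as.integer(q)) {
    stop("`p` and `q` must be single integers", call. = FALSE)
  }
  p <- as.integer(p)
  q <- as.integer(q)
  if (p < 2L || q < 2L) {
    stop("invalid shape: both image dimensions must be at least 2 (got ",
         p, " x ", q, ")", call. = FALSE)
  }
  structure(list(p = p, q = q), class = "image_shape")
}

#' @exportS3Method base::print
print.image_shape <- function(x, ...) {
  cat("<image_shape> ", x$p, " x ", x$q, " (", x$p * x$q, " pixels)\n",
      sep = "")
  invisible(x)
}

# Accept an image_shape, a length-2 numeric, or a matrix whose dim is used.
as_image_shape <- function(shape) {
  if (inherits(shape, "image_shape")) return(shape)
  if (is.matrix(shape)) return(image_shape(nrow(shape), ncol(shape)))
  if (is.numeric(shape) && length(shape) == 2L) {
    return(image_shape(shape[1L], shape[2L]))
  }
  stop("cannot interpret `shape` as an image shape", call. = FALSE)
}

#' Vectorize / unvectorize a coefficient image
#'
#' The package fixes a column-major vectorization convention: pixel (j, k)
#' of a p x q image maps to index p(k-1) + j of the coefficient vector
#' (R's native matrix layout).  All linear algebra, the difference operator
#' and the solver rely on this convention.
#'
#' @param B a p x q numeric matrix (coefficient image).
#' @param beta a numeric vector of length p*q.
#' @param shape an [image_shape()] (or anything coercible to one).
#' @return `vec_image` returns a numeric vector of length p*q;
#'   `unvec_image` returns a p x q matrix.
#' @examples
#' B <- matrix(1:6, 2, 3)
#' identical(unvec_image(vec_image(B), c(2, 3)), B)
#' @export
vec_image <- function(B) {
  if (!is.matrix(B) || !is.numeric(B)) {
    stop("`B` must be a numeric matrix", call. = FALSE)
  }
  as.vector(B)
}

#' @rdname vec_image
#' @export
unvec_image <- function(beta, shape) {
  shape <- as_image_shape(shape)
  if (length(beta) != shape$p * shape$q) {
    stop("length of `beta` (", length(beta), ") does not match shape ",
         shape$p, " x ", shape$q, call. = FALSE)
  }
  matrix(beta, shape$p, shape$q)
}

#' Discrete gradient of a coefficient image
#'
#' Returns the forward-difference gradient field of an image: at pixel
#' (j, k) the vertical component is b\[j+1, k\] - b\[j, k\] and the
#' horizontal component is b\[j, k+1\] - b\[j, k\].  Components pointing
#' outside the image (last row / last column) are zero, so the corner
#' (p, q) has gradient (0, 0).
#'
#' @param B a p x q numeric matrix with p, q >= 2.
#' @return A p x q x 2 array; slice `[,,1]` holds vertical differences,
#'   slice `[,,2]` horizontal differences.
#' @examples
#' gradient_image(matrix(c(0, 0, 1, 1), 2, 2))
#' @export
gradient_image <- function(B) {
  shape <- as_image_shape(B)
  p <- shape$p; q <- shape$q
  g <- array(0, dim = c(p, q, 2L))
  g[-p, , 1L] <- B[-1L, , drop = FALSE] - B[-p, , drop = FALSE]
  g[, -q, 2L] <- B[, -1L, drop = FALSE] - B[, -q, drop = FALSE]
  g
}

#' Discrete Sobolev norm of a coefficient image
#'
#' The L2 norm of the discrete gradient field,
#' \eqn{\|B\|_{Sob} = (\sum_{j,k} \|(\nabla B)_{jk}\|^2)^{1/2}}.
#' It is zero exactly for constant images, and its square equals the
#' quadratic form `t(beta) %*% K %*% beta` with `K` the grid-graph
#' Laplacian built by [build_difference_operator()].
#'
#' @inheritParams gradient_image
#' @return A single nonnegative number.
#' @examples
#' sobolev_norm(matrix(c(0, 0, 1, 1), 2, 2))  # sqrt(2)
#' @export
sobolev_norm <- function(B) {
  sqrt(sum(gradient_image(B)^2))
}

#' Sparse adjacent-pixel difference operator
#'
#' Builds the (2pq - p - q) x pq sparse matrix `D` whose rows are the
#' signed differences of 4-adjacent pixels of a p x q image (vectorized
#' column-major), together with its Gram matrix `K = t(D) %*% D`, the
#' combinatorial Laplacian of the p x q 4-neighbour lattice.
#'
#' Row ordering is fixed and reproducible: for each column k = 1..q-1 a
#' block of 2p - 1 rows interleaves the p - 1 vertical differences within
#' column k with the p - 1 horizontal differences from column k to k + 1,
#' ending with the horizontal difference at the last row; a final block
#' holds the p - 1 vertical differences within the last column.
#'
#' @param shape an [image_shape()] or length-2 integer vector `c(p, q)`.
#' @return An object of class `difference_operator`: a list with elements
#'   `shape`, `D` (sparse `dgCMatrix`) and `K` (sparse symmetric Laplacian).
#' @examples
#' op <- build_difference_operator(c(3, 3))
#' dim(op$D)  # 15 x 9
#' @export
build_difference_operator <- function(shape) {
  shape <- as_image_shape(shape)
  p <- shape$p; q <- shape$q
  nrowD <- 2L * p * q - p - q

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(i, j, v) {
    rows <<- c(rows, i); cols <<- c(cols, j); vals <<- c(vals, v)
  }

  for (k in seq_len(q - 1L)) {
    base_i <- (2L * p - 1L) * (k - 1L)
    if (p >= 2L) {
      # odd s: vertical differences within column k
      s <- seq(1L, 2L * p - 3L, by = 2L)
      j <- p * (k - 1L) + (s + 1L) %/% 2L
      add(base_i + s, j, rep(-1, length(s)))
      add(base_i + s, j + 1L, rep(1, length(s)))
      # even s: horizontal differences, column k to k + 1
      s <- seq(2L, 2L * p - 2L, by = 2L)
      j <- p * (k - 1L) + s %/% 2L
      add(base_i + s, j, rep(-1, length(s)))
      add(base_i + s, j + p, rep(1, length(s)))
    }
    # horizontal difference at the last row of column k
    add((2L * p - 1L) * k, k * p, -1)
    add((2L * p - 1L) * k, k * p + p, 1)
  }
  # vertical differences within the last column
  i <- seq((2L * p - 1L) * (q - 1L) + 1L, nrowD)
  j <- i - (p - 1L) * (q - 1L)
  add(i, j, rep(-1, length(i)))
  add(i, j + 1L, rep(1, length(i)))

  D <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(nrowD, p * q))
  K <- Matrix::crossprod(D)
  structure(list(shape = shape, D = D, K = K),
            class = "difference_operator")
}

#' @exportS3Method base::print
print.difference_operator <- function(x, ...) {
  cat("<difference_operator> for a ", x$shape$p, " x ", x$shape$q,
      " image\n  D: ", nrow(x$D), " x ", ncol(x$D),
      " sparse differences; K = t(D) D (lattice Laplacian)\n", sep = "")
  invisible(x)
}

#' Sobolev quadratic penalty
#'
#' Evaluates `t(beta) %*% K %*% beta` through sparse products; equal to
#' `sobolev_norm(unvec_image(beta, shape))^2`.
#'
#' @param beta numeric coefficient vector of length p*q.
#' @param op a `difference_operator` from [build_difference_operator()].
#' @return A single nonnegative number.
#' @export
quadratic_penalty <- function(beta, op) {
  stopifnot(inherits(op, "difference_operator"))
  if (length(beta) != ncol(op$K)) {
    stop("length of `beta` (", length(beta),
         ") does not match the operator's pixel count (", ncol(op$K), ")",
         call. = FALSE)
  }
  as.numeric(sum(beta * (op$K %*% beta)))
}

#' Export a sparse matrix as coordinate-format text
#'
#' Writes `row col value` triplets (0-based indices, tab-separated, with a
#' header line) for inspection of `D` or `K` outside R.
#'
#' @param M a sparse matrix, or a `difference_operator` whose `D` is used.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_sparse_coords <- function(M, path) {
  if (inherits(M, "difference_operator")) M <- M$D
  trip <- methods::as(methods::as(M, "CsparseMatrix"), "TsparseMatrix")
  df <- data.frame(row = trip@i, col = trip@j, value = trip@x)
  df <- df[order(df$row, df$col), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
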