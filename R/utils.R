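#' @importFrom rlang %||% abort .data
#' @importFrom stats rnorm runif sd median
#' @importFrom utils head tail
NULL

# consistent internal conventions:
#   physical coords in um: x along image columns, y along rows, z axial
#   voxel arrays have dim c(ny, nx, nz); voxel (i, j, k) center is at
#   ((j - 0.5) * px, (i - 0.5) * px, (k - 0.5) * zstep) + origin
#   4D stacks have dim c(ny, nx, nz, nt)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# evaluate `code` under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# shift a matrix by (dy, dx) with edge replication
shift_edge <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# reflect-pad a matrix by r pixels on every side (no edge duplication)
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) abort("padding radius exceeds image size")
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  m[ri, ci, drop = FALSE]
}

voxel_volume <- function(voxel) prod(voxel)

#' @keywords internal
"_PACKAGE"
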