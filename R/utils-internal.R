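`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible secondary seed for an independent stream, kept
# within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + as.double(k) * 1000003) %% 2147483647)
}

# Symmetric (half-sample mirror) padding: the edge row/column is repeated,
# i.e. pad indices are r, r-1, ..., 1 on the leading side.
mirror_pad <- function(x, pad_rows, pad_cols) {
  nr <- nrow(x); nc <- ncol(x)
  if (pad_rows > nr || pad_cols > nc)
    stop("padding exceeds image extent")
  ri <- c(rev(seq_len(pad_rows)), seq_len(nr), nr + 1L - seq_len(pad_rows))
  ci <- c(rev(seq_len(pad_cols)), seq_len(nc), nc + 1L - seq_len(pad_cols))
  x[ri, ci, drop = FALSE]
}

# 2-D "same"-size convolution with mirror boundary handling, computed in the
# Fourier domain.  Kernels used here (disc, Gaussian) are symmetric, so
# convolution and correlation coincide.  Kernel dimensions must be odd.
conv2_mirror <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  xp <- mirror_pad(x, kr, kc)
  nr <- nrow(xp) + nrow(kernel) - 1L
  nc <- ncol(xp) + ncol(kernel) - 1L
  A <- matrix(0, nr, nc)
  A[seq_len(nrow(xp)), seq_len(ncol(xp))] <- xp
  B <- matrix(0, nr, nc)
  B[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  out <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (nr * nc)
  out[2L * kr + seq_len(nrow(x)), 2L * kc + seq_len(ncol(x)), drop = FALSE]
}

# Circular (disc) window indicator of the given pixel radius.
disc_kernel <- function(radius) {
  r <- as.integer(radius)
  d <- (-r):r
  k <- outer(d, d, function(i, j) as.numeric(i * i + j * j <= r * r))
  k
}

# Normalized Gaussian kernel truncated at 3 sigma.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  d <- (-r):r
  k <- outer(d, d, function(i, j) exp(-(i * i + j * j) / (2 * sigma^2)))
  k / sum(k)
}

# Coerce a flow_map object or a plain 0/1 matrix to a binary integer matrix.
as_flow_pixels <- function(flow) {
  p <- if (inherits(flow, "flow_map")) flow$pixels else flow
  if (!is.matrix(p)) stop("'flow' must be a flow_map or a binary matrix")
  if (!all(p %in% c(0, 1))) stop("flow pixels must be 0/1")
  p
}
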