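# Separable 2D filtering with symmetric (edge-including reflective)
# boundary handling.  Symmetric padding with a normalized symmetric
# kernel conserves the image total exactly, which the support-blur and
# window-statistic contracts rely on.

pad_symmetric <- function(x, r) {
  if (r == 0) return(x)
  n <- nrow(x); m <- ncol(x)
  if (r > n || r > m)
    stop("filter radius exceeds image size", call. = FALSE)
  x <- rbind(x[r:1, , drop = FALSE], x, x[n:(n - r + 1), , drop = FALSE])
  cbind(x[, r:1, drop = FALSE], x, x[, m:(m - r + 1), drop = FALSE])
}

# 1D kernel applied along rows then columns (kernel length odd).
filter_sep <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- pad_symmetric(x, r)
  rows <- r + seq_len(n); cols <- r + seq_len(m)
  tmp <- matrix(0, n, m + 2L * r)
  for (i in seq_along(k))                       # vertical pass
    tmp <- tmp + k[i] * xp[rows + (i - 1L - r), , drop = FALSE]
  out <- matrix(0, n, m)
  for (i in seq_along(k))                       # horizontal pass
    out <- out + k[i] * tmp[, cols + (i - 1L - r), drop = FALSE]
  out
}

box_kernel <- function(m) rep(1 / m, m)

gaussian_kernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

#' Gaussian blur with symmetric boundary handling
#'
#' Separable Gaussian filter (kernel truncated at four standard
#' deviations, normalized to unit sum).  With symmetric boundary
#' reflection the image total is conserved exactly.
#'
#' @param x Real matrix.
#' @param sigma Standard deviation in pixels; 0 returns `x` unchanged.
#' @return Filtered matrix of the same dimensions.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x))
  if (!is.finite(sigma) || sigma < 0)
    stop("gaussian_blur: sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(x)
  filter_sep(x, gaussian_kernel(sigma))
}
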