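# internal numerical helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
deg2rad <- function(x) x * pi / 180

#' @noRd
rad2deg <- function(x) x * 180 / pi

# complex analytic signal of a real vector along its length via the
# FFT half-spectrum method: positive-frequency components doubled,
# negative-frequency components zeroed, DC and Nyquist kept.
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# columnwise cubic-spline (or linear) interpolation of a matrix sampled at
# `x` onto `xout`.  Values requested outside [min(x), max(x)] are zero-filled.
#' @noRd
interp_columns <- function(x, y, xout, method = c("cubic", "linear")) {
  method <- match.arg(method)
  y <- as.matrix(y)
  inside <- xout >= min(x) & xout <= max(x)
  out <- matrix(0, nrow = length(xout), ncol = ncol(y))
  for (j in seq_len(ncol(y))) {
    out[inside, j] <- if (method == "cubic") {
      stats::spline(x, y[, j], xout = xout[inside], method = "fmm")$y
    } else {
      stats::approx(x, y[, j], xout = xout[inside])$y
    }
  }
  out
}

# centered running mean with edge truncation (window shrinks at the borders)
#' @noRd
running_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Savitzky-Golay smoothing, polynomial order 3, exact at the edges
# (asymmetric windows fitted explicitly).  Exact for global cubics.
#' @noRd
sg_smooth <- function(y, width, order = 3L) {
  n <- length(y)
  width <- as.integer(width)
  if (width %% 2 == 0) width <- width + 1L
  if (width < order + 2L || width >= n) return(y)
  half <- width %/% 2
  # central convolution weights for evaluating the fit at window center
  xs <- seq(-half, half)
  A <- outer(xs, 0:order, `^`)
  w_central <- (solve(crossprod(A), t(A)))[1, ]
  out <- y
  idx <- (half + 1):(n - half)
  conv <- stats::filter(y, rev(w_central), sides = 2)
  out[idx] <- conv[idx]
  # edges: fit an order-`order` polynomial to the first/last window and
  # evaluate at the uncovered points
  xs_edge <- seq_len(width)
  Ae <- outer(xs_edge, 0:order, `^`)
  cf <- solve(crossprod(Ae), t(Ae))
  beta_lo <- cf %*% y[1:width]
  beta_hi <- cf %*% y[(n - width + 1):n]
  out[1:half] <- (outer(1:half, 0:order, `^`) %*% beta_lo)[, 1]
  out[(n - half + 1):n] <-
    (outer((width - half + 1):width, 0:order, `^`) %*% beta_hi)[, 1]
  out
}

# 2D box filter with edge replication; kernel given as (rows, cols)
#' @noRd
box_filter <- function(img, kernel = c(2L, 3L)) {
  kr <- as.integer(kernel[1]); kc <- as.integer(kernel[2])
  nr <- nrow(img); nc <- ncol(img)
  # pad by replication
  pr_lo <- (kr - 1L) %/% 2L; pr_hi <- kr - 1L - pr_lo
  pc_lo <- (kc - 1L) %/% 2L; pc_hi <- kc - 1L - pc_lo
  ridx <- c(rep(1L, pr_lo), seq_len(nr), rep(nr, pr_hi))
  cidx <- c(rep(1L, pc_lo), seq_len(nc), rep(nc, pc_hi))
  p <- img[ridx, cidx, drop = FALSE]
  # summed-area table
  sat <- apply(apply(p, 2, cumsum), 1, cumsum)
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  out <- sat[r1 + kr, c1 + kc, drop = FALSE] - sat[r1, c1 + kc, drop = FALSE] -
    sat[r1 + kr, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  out / (kr * kc)
}

# quantile mapping of `x` onto the empirical distribution of `ref`
#' @noRd
histogram_match <- function(x, ref) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  q <- stats::quantile(ref, probs = (r - 1) / (n - 1), names = FALSE,
                       type = 7)
  out <- x
  out[] <- q
  out
}

# Shannon entropy of a nonnegative profile normalized to unit sum;
# low entropy = energy concentrated in few bins (sharp image)
#' @noRd
profile_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' @noRd
is_raw_frame <- function(x) inherits(x, "raw_frame")

#' @noRd
stopifnot_frame <- function(x) {
  if (!is_raw_frame(x)) stop("expected a 'raw_frame' object", call. = FALSE)
  invisible(x)
}
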