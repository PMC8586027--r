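# Internal helpers shared across modules.

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible(NULL)
}

assert_positive <- function(x, name) {
  abort_if(!is.numeric(x) || any(!is.finite(x)) || any(x <= 0),
           paste0("`", name, "` must be a positive finite number"))
}

#' @keywords internal
new_rendered_image <- function(mat, pixel_size_nm, origin_nm = c(0, 0)) {
  stopifnot(is.matrix(mat))
  structure(mat,
            pixel_size_nm = pixel_size_nm,
            origin_nm = origin_nm,
            class = c("rendered_image", "matrix", "array"))
}

pixel_size_of <- function(img) {
  p <- attr(img, "pixel_size_nm")
  abort_if(is.null(p), "image has no pixel size; pass one explicitly")
  p
}

origin_of <- function(img) attr(img, "origin_nm") %||% c(0, 0)

# Bilinear interpolation of a matrix at continuous (x, y) nm positions.
# Matrix rows index y, columns index x; pixel centers sit at
# (j - 0.5) * p + origin. Out-of-bounds samples return NA.
interp_bilinear <- function(img, x_nm, y_nm) {
  p <- pixel_size_of(img)
  o <- origin_of(img)
  cx <- (x_nm - o[1]) / p + 0.5   # continuous column coordinate
  cy <- (y_nm - o[2]) / p + 0.5
  j0 <- floor(cx); i0 <- floor(cy)
  fx <- cx - j0;   fy <- cy - i0
  nr <- nrow(img); nc <- ncol(img)
  ok <- j0 >= 1 & j0 + 1 <= nc & i0 >= 1 & i0 + 1 <= nr
  out <- rep(NA_real_, length(x_nm))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    v00 <- img[cbind(i0k, j0k)]
    v01 <- img[cbind(i0k, j0k + 1)]
    v10 <- img[cbind(i0k + 1, j0k)]
    v11 <- img[cbind(i0k + 1, j0k + 1)]
    out[ok] <- v00 * (1 - fxk) * (1 - fyk) + v01 * fxk * (1 - fyk) +
      v10 * (1 - fxk) * fyk + v11 * fxk * fyk
  }
  out
}

# Gaussian blur with replicated borders; kernel truncated at 4 sigma and
# capped at the image size (large-radius blurs then approach a global mean).
# Direct separable filtering for small kernels, FFT for large ones.
gaussian_blur <- function(img, sigma_px) {
  assert_positive(sigma_px, "sigma_px")
  half <- min(ceiling(4 * sigma_px), nrow(img) - 1, ncol(img) - 1)
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  pad <- half
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1, pad), seq_len(nr), rep(nr, pad))
  ci <- c(rep(1, pad), seq_len(nc), rep(nc, pad))
  big <- img[ri, ci, drop = FALSE]
  if (half <= 2) {
    big <- apply(big, 2, function(v) stats::filter(v, k, sides = 2))
    big <- t(apply(big, 1, function(v) stats::filter(v, k, sides = 2)))
  } else {
    # circular FFT convolution on the padded image; the padding removes
    # wrap-around contamination from the valid region
    wrap_kernel <- function(n) {
      v <- rep(0, n)
      v[1:(half + 1)] <- k[(half + 1):(2 * half + 1)]
      v[(n - half + 1):n] <- k[1:half]
      stats::fft(v)
    }
    FY <- wrap_kernel(nrow(big))
    FX <- wrap_kernel(ncol(big))
    big <- Re(stats::mvfft(stats::mvfft(big) * FY, inverse = TRUE)) / nrow(big)
    big <- t(Re(stats::mvfft(stats::mvfft(t(big)) * FX, inverse = TRUE)) / ncol(big))
  }
  out <- big[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
  out
}

# 3-point parabolic refinement of a discrete peak; returns sub-bin offset
# in (-0.5, 0.5). Degenerate curvature falls back to 0.
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(min(off, 0.5), -0.5)
}
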