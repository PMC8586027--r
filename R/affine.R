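#' 2D affine transforms for chromatic registration
#'
#' Two-colour localization data carry a smooth chromatic distortion between
#' channels; following standard practice it is modelled as an affine map
#' (scaling, rotation, shear, translation) fitted on multicolour fiducial
#' beads imaged in both channels.
#'
#' @param linear 2x2 matrix, the linear part (must be invertible).
#' @param translation length-2 numeric, translation in nm.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  abort_if(abs(det(linear)) <= 1e-12, "affine linear part is singular")
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine2d")
}

#' @rdname affine2d
#' @export
identity_affine <- function() affine2d()

#' Apply an affine transform to nm coordinates
#'
#' @param xy n x 2 matrix (or data frame with columns x, y) of points in nm.
#' @param transform An [affine2d()] object.
#' @return n x 2 matrix of transformed points.
#' @export
apply_affine <- function(xy, transform) {
  xy <- as.matrix(xy)
  out <- xy %*% t(transform$linear)
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  out
}

#' @rdname apply_affine
#' @export
invert_affine <- function(transform) {
  linv <- solve(transform$linear)
  affine2d(linv, -as.numeric(linv %*% transform$translation))
}

#' Fit the chromatic affine transform from matched bead positions
#'
#' Least-squares affine mapping the moving channel onto the reference
#' channel: differences in scaling, translation and rotation between the
#' two colour channels are absorbed into one 2x3 transform. Requires at
#' least three non-collinear matched pairs.
#'
#' @param ref n x 2 matrix of bead positions in the reference channel (nm).
#' @param moving n x 2 matrix of the same beads in the channel to correct.
#' @return An [affine2d()] with attribute `residual_rms_nm`.
#' @export
fit_chromatic_affine <- function(ref, moving) {
  ref <- as.matrix(ref); moving <- as.matrix(moving)
  abort_if(nrow(ref) != nrow(moving), "bead sets differ in length")
  abort_if(nrow(ref) < 3, "need at least 3 matched bead pairs")
  # collinearity check on the moving set
  centred <- sweep(moving, 2, colMeans(moving))
  sv <- svd(centred)$d
  abort_if(sv[2] < 1e-9 * max(sv[1], 1), "bead positions are collinear")
  X <- cbind(moving, 1)
  beta <- qr.solve(X, ref)           # 3 x 2: rows (a, b, t)
  tf <- affine2d(t(beta[1:2, , drop = FALSE]), beta[3, ])
  resid <- ref - apply_affine(moving, tf)
  attr(tf, "residual_rms_nm") <- sqrt(mean(rowSums(resid^2)))
  tf
}

#' Match beads across channels by mutual nearest neighbours
#'
#' @param a,b n x 2 matrices of candidate bead positions (nm).
#' @param max_dist_nm maximum pairing distance (default 300 nm).
#' @return list with matrices `a` and `b` of matched rows.
#' @export
match_beads <- function(a, b, max_dist_nm = 300) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  nn_ab <- apply(d2, 1, which.min)
  nn_ba <- apply(d2, 2, which.min)
  keep <- which(nn_ba[nn_ab] == seq_len(nrow(a)) &
                  d2[cbind(seq_len(nrow(a)), nn_ab)] <= max_dist_nm^2)
  list(a = a[keep, , drop = FALSE], b = b[nn_ab[keep], , drop = FALSE])
}
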