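## Closed-form least-squares rigid superposition (Kabsch).

#' Least-squares rigid superposition of paired points
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum || R x_i + t - y_i ||^2` over paired points, by SVD of the
#' cross-covariance matrix with the determinant sign corrected so the
#' transform is a rotation (no reflection).
#'
#' @param x,y Numeric matrices (n x 3) of source / target coordinates.
#' @return List with `rotation` (3x3), `translation` (length 3) and `rms`,
#'   the root-mean-square residual over the pairs after superposition.
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y), nrow(x) >= 1)
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  h <- crossprod(x0, y0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cy - as.vector(r %*% cx)
  res <- apply_rigid(x, r, t_vec) - y
  list(rotation = r, translation = t_vec,
       rms = sqrt(mean(rowSums(res^2))))
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 vector.
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid <- function(coords, rotation, translation) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

identity_transform <- function() {
  list(rotation = diag(3), translation = c(0, 0, 0))
}

## Random rotation matrix (uniform via QR of Gaussian), used by fixtures.
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
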