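#' Kabsch superposition
#'
#' Closed-form least-squares rigid superposition of two equal-size point
#' sets via singular value decomposition. By default the returned rotation
#' is proper (determinant +1); a reflection in the optimum is corrected by
#' sign-flipping the smallest singular direction.
#'
#' @param mobile,reference `n x 3` matrices, `n >= 3`, finite coordinates.
#' @param allow_reflection Allow an improper (det -1) transform if it fits
#'   better.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, after applying the transform to `mobile`), and `degenerate`
#'   (TRUE when the point set is collinear/coincident so the rotation is not
#'   unique; the closed-form solution is still returned). The transform maps
#'   `mobile` onto `reference` as `mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, allow_reflection = FALSE) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) stop("point sets differ in size")
  if (ncol(mobile) != 3) stop("points must be n x 3")
  if (nrow(mobile) < 3) stop("at least 3 points are required")
  if (!all(is.finite(mobile)) || !all(is.finite(reference))) {
    stop("non-finite coordinates")
  }

  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                    # covariance, mobile -> reference
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, if (allow_reflection) 1 else d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- as.numeric(cr - R %*% cm)

  # collinear/coincident sets leave the rotation about the degenerate axis
  # free; flag rather than error, sampled gap geometries can come close
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)

  moved <- sweep(mobile %*% t(R), 2, translation, "+")
  list(rotation = R, translation = translation,
       rmsd = rmsd(moved, reference), degenerate = degenerate)
}

#' Root-mean-square deviation between point sets
#'
#' @param a,b `n x 3` matrices of matched points.
#' @param superpose Optimally superpose `a` onto `b` first (Kabsch); without
#'   it, the raw coordinate deviation is returned.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("point sets differ in size")
  if (nrow(a) < 1) stop("empty point sets")
  if (superpose) return(kabsch_superpose(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Idealized virtual C-beta position
#'
#' Places a C-beta from the backbone N, CA and C atoms using ideal
#' tetrahedral geometry (the standard fixed linear combination of the
#' CA->N, CA->C and normal directions). Used for all pairwise features so
#' glycine and designed positions are treated uniformly. The CA-CB distance
#' is a fixed constant (about 1.53 Angstrom) independent of the input.
#'
#' @param N,CA,C Length-3 vectors or `n x 3` matrices (rows matched).
#' @return C-beta coordinates with the same shape as the inputs.
#' @export
virtual_cb <- function(N, CA, C) {
  vecs <- lapply(list(N = N, CA = CA, C = C), function(v) {
    v <- if (is.matrix(v)) v else matrix(v, nrow = 1)
    stopifnot(ncol(v) == 3, all(is.finite(v)))
    v
  })
  N <- vecs$N; CA <- vecs$CA; C <- vecs$C
  b <- CA - N
  c <- C - CA
  a <- row_cross(b, c)
  an <- sqrt(rowSums(a^2))
  if (any(an < 1e-8)) stop("collinear or coincident N/CA/C atoms")
  CB <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c + CA
  if (nrow(CB) == 1 && !is.matrix(N)) CB <- drop(CB)
  CB
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# dihedral p1-p2-p3-p4 in degrees, rows matched; range (-180, 180]
row_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

# planar angle p1-p2-p3 in degrees, [0, 180]
row_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Radius of gyration of the CA trace
#'
#' @param x A [backbone] structure.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x) {
  ca <- x$CA
  sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
}
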