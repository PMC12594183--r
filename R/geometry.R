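#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' least-squares deviation of `mobile %*% R + t` from `ref` (row-vector
#' convention). If the optimal orthogonal matrix would be a reflection
#' (det = -1), the axis of smallest singular value is flipped so chirality is
#' preserved. Rank-deficient (collinear or coincident) point sets are flagged
#' `degenerate` and fitted by translation only.
#'
#' @param mobile,ref n x 3 coordinate matrices with matched rows (n >= 3).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (post-fit, in the units of the input), and `degenerate` flag.
#' @examples
#' p <- matrix(rnorm(12), 4, 3)
#' kabsch(p + 5, p)$rmsd   # pure translation -> 0
#' @export
kabsch <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (!all(dim(mobile) == dim(ref)) || ncol(mobile) != 3L)
    stop("dimension error: point sets must be matched n x 3 matrices")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  C <- crossprod(A, B)                    # 3x3 covariance
  sv <- svd(C)
  degenerate <- sum(sv$d > max(sv$d[1], 1e-12) * 1e-8) < 2
  if (degenerate) {
    R <- diag(3)
  } else {
    d <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  t_vec <- cr - as.numeric(cm %*% R)
  fitted <- mobile %*% R + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - ref)^2))),
       degenerate = degenerate)
}

#' Apply a rigid transform to coordinates or a structure frame
#'
#' @param x n x 3 matrix or a `struct`.
#' @param transform result of [kabsch()] (fields `rotation`, `translation`).
#' @param frame frame to transform when `x` is a `struct` (default: all).
#' @return object of the same type as `x`.
#' @export
apply_transform <- function(x, transform, frame = NULL) {
  tr <- function(m) m %*% transform$rotation +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (inherits(x, "struct")) {
    frames <- frame %||% seq_len(nframes(x))
    for (fr in frames) x <- set_coords(x, tr(coords(x, fr)), fr)
    x
  } else tr(as.matrix(x))
}

#' Plain coordinate RMSD between matched point sets
#'
#' @param a,b matched n x 3 matrices.
#' @return RMSD in input units.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Mirrors the common backbone-RMSD equilibration diagnostic: each frame is
#' compared with `ref_frame` over `sel`, optionally after optimal
#' superposition ([kabsch()]).
#'
#' @param traj multi-frame `struct`.
#' @param ref_frame reference frame index (default 1, "first frame of
#'   production").
#' @param sel a [selection()]; default backbone N, CA, C, O.
#' @param fit superpose each frame before measuring? Default TRUE.
#' @return numeric vector, one RMSD (set units, Å) per frame.
#' @export
rmsd_series <- function(traj, ref_frame = 1L, sel = sel_backbone(),
                        fit = TRUE) {
  i <- select_idx(traj, sel)
  if (length(i) == 0) stop("empty selection")
  sub <- select_atoms(traj, sel)
  ref <- coords(sub, ref_frame)
  vapply(seq_len(nframes(sub)), function(fr) {
    m <- coords(sub, fr)
    if (fit) kabsch(m, ref)$rmsd else rmsd(m, ref)
  }, 0)
}

#' Geometric center of a selection
#'
#' Unweighted mean of the selected atom coordinates (geometric center, not
#' center of mass — no mass weighting anywhere in this package).
#'
#' @param x a `struct`.
#' @param sel a [selection()].
#' @param frame frame index.
#' @return length-3 numeric vector (Å).
#' @export
geometric_center <- function(x, sel = selection(), frame = 1L) {
  i <- select_idx(x, sel)
  if (length(i) == 0) stop("empty selection")
  colMeans(coords(x, frame)[i, , drop = FALSE])
}

#' Angle at vertex b of the triple (a, b, c)
#'
#' Used for the inter-domain (e.g. NTD–CD–substrate) angle computed from
#' domain geometric centers.
#'
#' @param a,b,c length-3 coordinate vectors; `b` is the vertex.
#' @return angle in degrees, in [0, 180].
#' @export
interdomain_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length arm at angle vertex")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}
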