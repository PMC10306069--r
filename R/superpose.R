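# Least-squares rigid superposition (Kabsch).

#' Optimal superposition of two ordered point sets
#'
#' Finds the proper rotation R (det = +1) and translation t minimizing
#' ||mov R' + t - ref||; returns the minimized r.m.s.d.
#'
#' @param ref,mov n x 3 matrices of paired points, n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   and `fitted` (mov after superposition).
#' @export
superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3L || ncol(mov) != 3L)
    stop("ref and mov must be equal-length n x 3 matrices")
  n <- nrow(ref)
  if (n < 3L) stop("degenerate superposition: need at least 3 points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  ref_c <- sweep(ref, 2L, cr); mov_c <- sweep(mov, 2L, cm)
  if (max(svd(ref_c)$d) < 1e-9 || max(svd(mov_c)$d) < 1e-9 ||
      svd(ref_c)$d[2L] < 1e-9 || svd(mov_c)$d[2L] < 1e-9)
    stop("degenerate superposition: collinear or coincident points")
  H <- t(mov_c) %*% ref_c
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- mov_c %*% t(Rm)
  rmsd <- sqrt(mean(rowSums((fitted - ref_c)^2)))
  fitted <- sweep(fitted, 2L, cr, `+`)
  list(rotation = Rm, translation = cr - drop(Rm %*% cm), rmsd = rmsd,
       fitted = fitted)
}
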