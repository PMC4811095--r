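## Discrete TGV^2 calculus: forward differences with periodic boundaries,
## the symmetrized gradient and their adjoints, plus the two isotropic
## shrinkage (proximal) operators used by the splitting scheme.
##
## Conventions: D1 differences along the first array index (rows), D2 along
## the second (columns), both circular. A vector field is a list(p1, p2); a
## symmetric 2x2 tensor field stores (z1, z2, z3) for [[z1, z3], [z3, z2]].

shift_down <- function(m) m[c(2:nrow(m), 1L), , drop = FALSE]   # u(i+1, j)
shift_up   <- function(m) m[c(nrow(m), 1:(nrow(m) - 1L)), , drop = FALSE]
shift_right<- function(m) m[, c(2:ncol(m), 1L), drop = FALSE]   # u(i, j+1)
shift_left <- function(m) m[, c(ncol(m), 1:(ncol(m) - 1L)), drop = FALSE]

d1 <- function(u) shift_down(u) - u
d2 <- function(u) shift_right(u) - u
d1t <- function(u) shift_up(u) - u    # adjoint of d1 (negative backward diff)
d2t <- function(u) shift_left(u) - u

#' Discrete gradient with periodic boundaries
#'
#' Forward finite differences along both axes with periodic wrap-around:
#' `grad(u) = (D1 u, D2 u)`.
#'
#' @param u complex square matrix.
#' @return vector field: list with components `p1`, `p2`.
#' @export
grad <- function(u) list(p1 = d1(u), p2 = d2(u))

#' Negative adjoint pair of [grad()]
#'
#' `div_field(p)` is `-D^T p = -(D1^T p1 + D2^T p2)`, so
#' `<grad(u), p> == <u, -div_field(p)>`.
#'
#' @param p vector field (list with `p1`, `p2`).
#' @return complex matrix.
#' @export
div_field <- function(p) -(d1t(p$p1) + d2t(p$p2))

#' Symmetrized gradient of a vector field
#'
#' The discrete symmetric-derivative operator of the TGV^2 model:
#' `z1 = D1 p1`, `z2 = D2 p2`, `z3 = (D2 p1 + D1 p2) / 2`, representing the
#' per-pixel symmetric matrix `[[z1, z3], [z3, z2]]`.
#'
#' @param p vector field.
#' @return symmetric tensor field: list with `z1`, `z2`, `z3`.
#' @export
sym_grad <- function(p) list(z1 = d1(p$p1), z2 = d2(p$p2),
                             z3 = (d2(p$p1) + d1(p$p2)) / 2)

#' Adjoint of [sym_grad()] under the weighted Frobenius inner product
#'
#' With the tensor inner product counting the off-diagonal twice
#' (`<z, w> = sum(z1 w1) + sum(z2 w2) + 2 sum(z3 w3)`), `sym_div` satisfies
#' `<sym_grad(p), z> == <p, sym_div(z)>`.
#'
#' @param z symmetric tensor field.
#' @return vector field.
#' @export
sym_div <- function(z) list(p1 = d1t(z$z1) + d2t(z$z3),
                            p2 = d2t(z$z2) + d1t(z$z3))

#' Isotropic vector soft-thresholding
#'
#' The proximal map of `thr * ||.||_2` applied per pixel to a 2-vector field:
#' zero when the pixel magnitude `sqrt(|a1|^2 + |a2|^2)` is at most `thr`,
#' otherwise the vector scaled by `(mag - thr) / mag`. Complex components are
#' scaled by the same real factor.
#'
#' @param p vector field (list with `p1`, `p2`).
#' @param thr nonnegative threshold.
#' @return thresholded vector field.
#' @export
shrink2 <- function(p, thr) {
  if (thr < 0) stop("threshold must be nonnegative")
  mag <- sqrt(Mod(p$p1)^2 + Mod(p$p2)^2)
  sc <- ifelse(mag > thr, (mag - thr) / pmax(mag, .Machine$double.eps), 0)
  list(p1 = p$p1 * sc, p2 = p$p2 * sc)
}

#' Frobenius-norm soft-thresholding of a symmetric tensor field
#'
#' The proximal map of `thr * ||.||_F` per pixel, with the Frobenius norm of
#' the symmetric matrix counting the stored off-diagonal twice:
#' `||B||_F^2 = |z1|^2 + |z2|^2 + 2 |z3|^2`.
#'
#' @param z symmetric tensor field (list with `z1`, `z2`, `z3`).
#' @param thr nonnegative threshold.
#' @return thresholded tensor field.
#' @export
shrinkF <- function(z, thr) {
  if (thr < 0) stop("threshold must be nonnegative")
  mag <- sqrt(Mod(z$z1)^2 + Mod(z$z2)^2 + 2 * Mod(z$z3)^2)
  sc <- ifelse(mag > thr, (mag - thr) / pmax(mag, .Machine$double.eps), 0)
  list(z1 = z$z1 * sc, z2 = z$z2 * sc, z3 = z$z3 * sc)
}

#' Second-order TGV penalty value
#'
#' Evaluates `alpha1 * sum_l ||(grad(u) - p)(l)||_2 +
#' alpha0 * sum_l ||sym_grad(p)(l)||_F` (isotropic norms, matching the
#' shrinkage operators). With `p = 0` and `alpha = (1, 1)` the first term is
#' the classical isotropic total variation.
#'
#' @param u complex image matrix.
#' @param p vector field.
#' @param alpha0,alpha1 nonnegative weights of the second- and first-order
#'   terms.
#' @return nonnegative scalar.
#' @export
tgv2_penalty <- function(u, p, alpha0, alpha1) {
  if (alpha0 < 0 || alpha1 < 0) stop("weights must be nonnegative")
  g <- grad(u)
  e <- sym_grad(p)
  t1 <- sum(sqrt(Mod(g$p1 - p$p1)^2 + Mod(g$p2 - p$p2)^2))
  t2 <- sum(sqrt(Mod(e$z1)^2 + Mod(e$z2)^2 + 2 * Mod(e$z3)^2))
  alpha1 * t1 + alpha0 * t2
}
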