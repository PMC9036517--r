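#' Sigmoid membrane surface model
#'
#' The radially averaged height of the curved membrane is modelled by a
#' five-parameter generalized logistic ("sigmoid-like") curve
#' \deqn{h(r) = a + d \, \left(1 + e^{-b (r - x_0)}\right)^{-c}}
#' where `a` is the inner (pore-side) plateau height, `a + d` the outer
#' plateau (for `c = 1`), `b` the transition steepness, `c` an asymmetry
#' exponent and `x0` the transition midpoint. With `c = 1` the curve passes
#' through the midpoint of its two asymptotes at `r = x0`, and `d = 0`
#' collapses to a flat membrane.
#'
#' The first and second derivatives used for curvature are generated
#' symbolically from this expression (via [stats::D()]) at package build,
#' never transcribed by hand, so the curvature code cannot drift from the
#' height model.
#'
#' @param r numeric vector of radial distances (nm), `r >= 0`.
#' @param params named numeric vector or list with elements
#'   `a`, `b`, `c`, `d`, `x0`.
#' @return `surface_height()` returns `h(r)` in nm; `surface_deriv1()` and
#'   `surface_deriv2()` the analytic first and second derivatives.
#' @examples
#' p <- c(a = 12, b = 0.527, c = 1, d = 3, x0 = 8.5)
#' surface_height(c(0, 8.5, 25), p)
#' @export
surface_height <- function(r, params) {
  p <- check_profile_params(params)
  eval(.sigmoid_expr, c(p, list(x = r)))
}

# symbolic model and derivatives, generated once at load
.sigmoid_expr <- quote(a + d * (1 + exp(-b * (x - x0)))^(-c))
.sigmoid_d1 <- D(.sigmoid_expr, "x")
.sigmoid_d2 <- D(D(.sigmoid_expr, "x"), "x")

#' @rdname surface_height
#' @export
surface_deriv1 <- function(r, params) {
  p <- check_profile_params(params)
  v <- eval(.sigmoid_d1, c(p, list(x = r)))
  rep_len(v, length(r))
}

#' @rdname surface_height
#' @export
surface_deriv2 <- function(r, params) {
  p <- check_profile_params(params)
  v <- eval(.sigmoid_d2, c(p, list(x = r)))
  rep_len(v, length(r))
}

check_profile_params <- function(params) {
  p <- as.list(params)
  need <- c("a", "b", "c", "d", "x0")
  if (!all(need %in% names(p)))
    stopf("profile params must be named %s", paste(need, collapse = ", "))
  p <- p[need]
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stopf("non-finite profile parameter(s): %s",
          paste(need[!is.finite(vals)], collapse = ", "))
  p
}

# Signed curvature of the height profile: K = f'' / (1 + f'^2)^(3/2).
# Sign convention (fixed package-wide): K > 0 where the membrane curves
# toward the solvent-exposed side, i.e. the concave bowl as seen by a
# protein above the top leaflet; K < 0 on the convex shoulder.
surface_curvature <- function(r, params) {
  f1 <- surface_deriv1(r, params)
  f2 <- surface_deriv2(r, params)
  f2 / (1 + f1^2)^1.5
}
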