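#' The universal slow-passage constant
#'
#' The delayed escape from a dynamically crossed saddle-node is governed by a
#' universal constant: in rescaled coordinates the trajectory hugging the
#' attracting branch of the nullcline parabola is
#' \eqn{x = \zeta(y)} with denominator
#' \eqn{J_{-1/3}(2y^{3/2}/3) + J_{1/3}(2y^{3/2}/3)}, and the escape height is
#' set by the smallest positive zero \eqn{y^*} of that denominator. Following
#' the sign convention in which the spike-time corrections come out positive,
#' the constant is stored negative:
#' \deqn{\Omega_0 = -y^* \approx -2.33811.}
#' Through the identity
#' \eqn{\mathrm{Ai}(-y) = \tfrac{\sqrt{y}}{3}\,[J_{-1/3}(2y^{3/2}/3) +
#' J_{1/3}(2y^{3/2}/3)]}, \eqn{y^*} is also the first zero of the Airy
#' function \eqn{\mathrm{Ai}} reflected to the negative axis.
#'
#' @param method \code{"bessel"} (default) finds the zero of the Bessel
#'   combination by bracketed root finding; \code{"airy"} integrates the
#'   Airy equation \eqn{w'' = x w} from the exact gamma-function initial
#'   values at the origin and locates the first zero of
#'   \eqn{\mathrm{Ai}(-y)} — a route independent of \code{besselJ}, kept as
#'   a numerical cross-check.
#' @return \eqn{\Omega_0 < 0}, a length-one numeric.
#' @examples
#' slow_passage_constant()            # -2.338107...
#' @export
slow_passage_constant <- function(method = c("bessel", "airy")) {
  method <- match.arg(method)
  if (method == "bessel") {
    den <- function(y) {
      arg <- 2 * y^1.5 / 3
      besselJ(arg, -1/3) + besselJ(arg, 1/3)
    }
    # den(0+) = +Inf (J_{-1/3} diverges), first sign change near y = 2.3
    -stats::uniroot(den, c(1, 4), tol = 1e-14)$root
  } else {
    # Ai(0) = 3^{-2/3}/Gamma(2/3), Ai'(0) = -3^{-1/3}/Gamma(1/3);
    # integrate w'' = x w towards negative x and find the first zero.
    rhs <- function(t, w, p) list(c(w[2], -t * w[1]))  # t = -x = y > 0
    y0 <- c(3^(-2/3) / gamma(2/3), 3^(-1/3) / gamma(1/3))
    sol <- deSolve::ode(y0, seq(0, 4, by = 0.01), rhs, NULL,
                        method = "lsoda", rtol = 1e-12, atol = 1e-14)
    w <- sol[, 2]
    i <- which(w[-1] * w[-length(w)] < 0)[1]
    f <- function(y) {
      s <- deSolve::ode(y0, c(0, y), rhs, NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
      s[nrow(s), 2]
    }
    -stats::uniroot(f, c(sol[i, 1], sol[i + 1, 1]), tol = 1e-12)$root
  }
}
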