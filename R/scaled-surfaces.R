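#' Residual of a scaled-space surface condition
#'
#' The three "ostensibly neutral" surfaces are zero sets of weighted DFE
#' integrals over the scaled effect gamma = Tc s:
#' \describe{
#'   \item{v0}{`\int rho~(gamma) gamma e^gamma dgamma = 0` - mean fitness
#'     neither rises nor falls. The residual has the sign of Tc^2 v.}
#'   \item{fu}{`\int rho~(gamma) (e^gamma - 1) dgamma = 0` - the total
#'     selected fixation rate F equals the mutation rate U (a dN/dS = 1
#'     analogue). The residual has the sign of F - U.}
#'   \item{alpha0}{`\int rho~(gamma) (gamma e^gamma + 1 - e^gamma)/gamma
#'     dgamma = 0`, equivalently kernel `e^gamma - (e^gamma - 1)/gamma` -
#'     the McDonald-Kreitman-like alpha statistic vanishes (divergence
#'     excess exactly offsets the polymorphism excess).}
#' }
#'
#' @param sdfe a [scaled_dfe()].
#' @param surface `"v0"`, `"fu"` or `"alpha0"`.
#' @param method `"auto"` or `"quadrature"` (see [dfe_integral()]).
#' @return the residual (signed real number).
#' @export
surface_residual <- function(sdfe, surface = c("v0", "fu", "alpha0"),
                             method = "auto") {
  surface <- match.arg(surface)
  kernel <- switch(surface, v0 = "s_exp", fu = "exp_m1", alpha0 = "alpha")
  dfe_integral(sdfe, kernel, a = 1, method = method)
}

.surface_kernels <- list(
  v0 = list(kinds = "s_exp", signs = 1),
  fu = list(kinds = "exp", signs = 1, shift = -1),
  alpha0 = list(kinds = c("exp", "expm1_over_s"), signs = c(1, -1))
)

# normalised single-side surface integral I_side = E[K(gamma) | component]
.side_surface_integral <- function(family, scale, shape, surface, side,
                                   method = "auto") {
  k <- .surface_kernels[[surface]]
  val <- sum(k$signs * vapply(k$kinds, function(kind)
    .component_moment(family, scale, shape, NULL, kind, 1, side, method), 0))
  if (!is.null(k$shift)) val <- val + k$shift
  val
}

#' Beneficial fraction placing a point on a surface
#'
#' For a two-component scaled DFE at fixed (`gamma_b`, `gamma_d`), the
#' surface residual is linear in the mixture weights, so the ratio eta
#' that puts the point exactly on the surface is `-I_d / I_b`, the ratio
#' of the per-component kernel integrals. Closed forms:
#' two-effect v=0, `eta = gamma_d e^{-gamma_d} / (gamma_b e^{gamma_b})`;
#' two-effect F=U, `eta = (1 - e^{-gamma_d}) / (e^{gamma_b} - 1)`;
#' exponential v=0, `eta = (gamma_d/gamma_b) ((1-gamma_b)/(1+gamma_d))^2`
#' (requires `gamma_b < 1`; the integral diverges otherwise).
#'
#' @param gamma_b,gamma_d scaled effect scales (> 0).
#' @param family `"two_effect"` or `"exponential_pair"`.
#' @param surface `"v0"`, `"fu"` or `"alpha0"`.
#' @param method `"closed_form"` evaluates the component integrals in
#'   closed form; `"root_solve"` brackets and bisects the residual in
#'   log eta (the independent oracle); `"quadrature"` is `root_solve`
#'   with the residual forced through adaptive quadrature.
#' @param shape_b,shape_d gamma shapes (numeric-path families only).
#' @return eta >= 0 such that the surface residual vanishes.
#' @export
#' @examples
#' eta_on_surface(1, 1, "two_effect", "v0")  # exp(-2)
eta_on_surface <- function(gamma_b, gamma_d, family = "two_effect",
                           surface = c("v0", "fu", "alpha0"),
                           method = c("closed_form", "root_solve",
                                      "quadrature"),
                           shape_b = 1, shape_d = 1) {
  surface <- match.arg(surface)
  method <- match.arg(method)
  if (gamma_b <= 0 || gamma_d <= 0) stop("scaled effects must be positive")
  if (family == "exponential_pair" && surface == "v0" && gamma_b >= 1)
    stop_divergence("exponential beneficial component with gamma_b >= 1: the v=0 integral diverges")
  if (method == "closed_form") {
    ib <- .side_surface_integral(family, gamma_b, shape_b, surface, "b")
    id <- .side_surface_integral(family, gamma_d, shape_d, surface, "d")
    return(-id / ib)
  }
  int_method <- if (method == "quadrature") "quadrature" else "auto"
  resid <- function(log_eta) {
    sdfe <- scaled_dfe(family, gamma_b = gamma_b, gamma_d = gamma_d,
                       eta = exp(log_eta), shape_b = shape_b,
                       shape_d = shape_d)
    surface_residual(sdfe, surface, method = int_method)
  }
  # residual is monotone increasing in eta (mixture linearity): bracketed
  # bisection on log eta is safe
  lo <- log(1e-12); hi <- log(1e3)
  if (resid(lo) > 0 || resid(hi) < 0)
    stop("no eta in [1e-12, 1e3] places this point on the surface")
  exp(stats::uniroot(resid, c(lo, hi), tol = 1e-14)$root)
}

# golden-section maximisation on [lo, hi]; f unimodal
golden_section_max <- function(f, lo, hi, tol = 1e-10) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  xm <- (a + b) / 2
  list(maximum = xm, objective = f(xm))
}

#' Ridgeline of the v=0 surface
#'
#' Along a v=0 curve at fixed eta, the beneficial fraction required for
#' exact balance is maximised as a function of the scaled deleterious
#' effect at `gamma_d* = 1` - the effect size at which deleterious
#' mutations are maximally impactful (small effects fix but cost little,
#' large effects are purged). `ridgeline()` returns the analytic ridge
#' point for a given eta: for the two-effect family
#' `gamma_b* = W(1/(e eta))` with W the Lambert function; for the
#' exponential pair `gamma_b* = 1 + 2 eta - 2 sqrt(eta^2 + eta)`.
#'
#' `ridgeline_gamma_d()` instead fixes `gamma_b` and locates the argmax of
#' `eta_on_surface(gamma_b, gamma_d, ...)` over `gamma_d` numerically
#' (coarse log-scan then golden-section search) - an independent check
#' that returns 1 for both supported families.
#'
#' @param family `"two_effect"` or `"exponential_pair"`.
#' @param eta beneficial-to-deleterious mutation-rate ratio (> 0).
#' @return `ridgeline()`: named vector `c(gamma_d_star, gamma_b_star)`.
#' @export
#' @examples
#' ridgeline("two_effect", eta = 1)  # gamma_b* = W(1/e) ~ 0.2785
ridgeline <- function(family = c("two_effect", "exponential_pair"), eta) {
  family <- match.arg(family)
  if (eta <= 0) stop("eta must be positive")
  gb <- if (family == "two_effect") {
    pracma::lambertWp(1 / (exp(1) * eta))
  } else {
    1 + 2 * eta - 2 * sqrt(eta^2 + eta)
  }
  c(gamma_d_star = 1, gamma_b_star = gb)
}

#' @rdname ridgeline
#' @param gamma_b fixed scaled beneficial effect (scale).
#' @param interval search interval for gamma_d.
#' @param method how eta is evaluated at each gamma_d (see
#'   [eta_on_surface()]).
#' @param tol absolute tolerance on the argmax.
#' @return `ridgeline_gamma_d()`: list with `gamma_d_star` and `eta_max`.
#' @export
ridgeline_gamma_d <- function(family = "two_effect", gamma_b,
                              interval = c(0.01, 10),
                              method = "closed_form", tol = 1e-10) {
  f <- function(gd) eta_on_surface(gamma_b, gd, family, "v0", method = method)
  # coarse scan to bracket the mode before golden-section refinement
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 41))
  vals <- vapply(grid, f, 0)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  res <- golden_section_max(f, lo, hi, tol = max(tol, 1e-5))
  xm <- res$maximum
  # the maximum is quadratically flat, so small evaluation noise limits
  # direct search accuracy; polish by root-finding the central-difference
  # gradient, whose sign change is sharp
  for (h in c(1e-3, if (method == "quadrature") 2e-4 else 1e-5)) {
    grad <- function(x) f(x + h) - f(x - h)
    glo <- xm - 10 * h; ghi <- xm + 10 * h
    if (glo > interval[1] && ghi < interval[2] &&
        sign(grad(glo)) != sign(grad(ghi))) {
      xm <- stats::uniroot(grad, c(glo, ghi), tol = min(tol, 1e-10))$root
    }
  }
  list(gamma_d_star = xm, eta_max = f(xm))
}

#' Always-adapt threshold for the scaled beneficial effect
#'
#' For a two-effect DFE at fixed eta, v > 0 for every gamma_d once
#' `gamma_b > gamma_b* = W(1/(e eta))`: no deleterious effect size can
#' drive the population into fitness decline. W is the principal Lambert
#' function, with large-argument behaviour `W(x) ~ log x - log log x`.
#'
#' @param eta beneficial-to-deleterious mutation-rate ratio (> 0).
#' @return the threshold scaled beneficial effect.
#' @export
adaptation_threshold <- function(eta) {
  if (any(eta <= 0)) stop("eta must be positive")
  vapply(eta, function(e) pracma::lambertWp(1 / (exp(1) * e)), 0)
}

#' Ordering of the three surface etas
#'
#' At fixed (`gamma_b`, `gamma_d`) the beneficial fractions required to
#' sit on the three surfaces are strictly ordered,
#' `eta(v=0) < eta(alpha=0) < eta(F=U)`: on the alpha = 0 surface the
#' population is still adapting (v > 0) while fixing fewer selected
#' mutations than neutral expectation (F < U), and on the v = 0 surface
#' alpha < 0 and F < U.
#'
#' @inheritParams eta_on_surface
#' @return named vector `c(eta_v0, eta_alpha0, eta_fu)`.
#' @export
surface_ordering <- function(gamma_b, gamma_d, family = "two_effect",
                             method = "closed_form",
                             shape_b = 1, shape_d = 1) {
  c(eta_v0 = eta_on_surface(gamma_b, gamma_d, family, "v0", method,
                            shape_b, shape_d),
    eta_alpha0 = eta_on_surface(gamma_b, gamma_d, family, "alpha0", method,
                                shape_b, shape_d),
    eta_fu = eta_on_surface(gamma_b, gamma_d, family, "fu", method,
                            shape_b, shape_d))
}

#' Divergence boundary of the exponential beneficial integral
#'
#' For an exponential beneficial component with mean scaled effect
#' gamma_b, the v=0 kernel integral `\int rho~_b(gamma) gamma e^gamma
#' dgamma` has integrand tail `~ e^{gamma (1 - 1/gamma_b)}`: it converges
#' exactly when the tail exponent `1 - 1/gamma_b` is negative. This
#' function classifies candidate means by that tail exponent and bisects
#' the convergent/divergent boundary, which sits at mean scaled effect 1.
#'
#' @param interval bracketing interval for the boundary.
#' @param tol bisection tolerance.
#' @return the localized divergence boundary (mean scaled effect).
#' @export
divergence_threshold <- function(interval = c(0.5, 1.5), tol = 1e-6) {
  tail_exponent <- function(gamma_b) 1 - 1 / gamma_b
  lo <- interval[1]; hi <- interval[2]
  if (tail_exponent(lo) >= 0 || tail_exponent(hi) < 0)
    stop("interval must bracket the convergence boundary")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tail_exponent(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
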