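#' Distributions of fitness effects
#'
#' A `dfe_spec` describes the distribution rho(s) of fitness effects of new
#' mutations, split into a beneficial component (s > 0) and a deleterious
#' component (s < 0) with mutation-rate ratio `eta` = Ub/Ud. By convention
#' both scale parameters `sb` and `sd` are positive; deleterious effects
#' enter every formula as negative s. Mixture weights are eta/(1+eta) for
#' the beneficial component and 1/(1+eta) for the deleterious component.
#'
#' Supported families:
#' \describe{
#'   \item{two_effect}{all beneficial mutations have effect `sb`, all
#'     deleterious mutations effect `-sd` (point masses).}
#'   \item{exponential_pair}{|s| exponentially distributed with means `sb`
#'     (beneficial) and `sd` (deleterious).}
#'   \item{gamma_pair}{|s| gamma distributed with means `sb`, `sd` and
#'     shapes `shape_b`, `shape_d`; handled by adaptive quadrature.}
#'   \item{tabulated}{discrete atoms at signed effects `table$s` with
#'     weights `table$weight` (normalised to sum to 1); `eta` is derived
#'     from the weight on s > 0 versus s < 0.}
#' }
#'
#' @param family one of `"two_effect"`, `"exponential_pair"`,
#'   `"gamma_pair"`, `"tabulated"`.
#' @param sb,sd positive scale of beneficial / deleterious effects
#'   (per-generation fitness units; the effect itself for `two_effect`,
#'   the mean |s| otherwise).
#' @param eta ratio Ub/Ud of beneficial to deleterious mutation rates
#'   (>= 0). `eta <= 1` is typical.
#' @param shape_b,shape_d gamma shapes (only used by `gamma_pair`).
#' @param table data.frame with columns `s` and `weight` (only
#'   `tabulated`).
#' @return an object of class `dfe_spec`.
#' @export
#' @examples
#' dfe_spec("two_effect", sb = 1e-4, sd = 2e-4, eta = 0.1)
dfe_spec <- function(family = c("two_effect", "exponential_pair",
                                "gamma_pair", "tabulated"),
                     sb = NULL, sd = NULL, eta = NULL,
                     shape_b = 1, shape_d = 1, table = NULL) {
  family <- match.arg(family)
  if (family == "tabulated") {
    if (is.null(table) || !all(c("s", "weight") %in% names(table)))
      stop("tabulated DFE requires a table with columns 's' and 'weight'")
    if (any(table$weight < 0)) stop("tabulated weights must be non-negative")
    table <- data.frame(s = as.numeric(table$s),
                        weight = table$weight / sum(table$weight))
    wb <- sum(table$weight[table$s > 0])
    wd <- sum(table$weight[table$s < 0])
    eta <- if (wd > 0) wb / wd else Inf
    sb <- if (wb > 0) sum(table$s[table$s > 0] * table$weight[table$s > 0]) / wb else NA_real_
    sd <- if (wd > 0) -sum(table$s[table$s < 0] * table$weight[table$s < 0]) / wd else NA_real_
  } else {
    if (is.null(sb) || is.null(sd) || is.null(eta))
      stop("sb, sd and eta are required for parametric families")
    if (sb <= 0 || sd <= 0) stop("scales sb and sd must be positive")
    if (eta < 0) stop("eta must be non-negative")
    if (family == "gamma_pair" && (shape_b <= 0 || shape_d <= 0))
      stop("gamma shapes must be positive")
  }
  structure(list(family = family, sb = sb, sd = sd, eta = eta,
                 shape_b = shape_b, shape_d = shape_d, table = table),
            class = "dfe_spec")
}

#' Scaled distribution of fitness effects
#'
#' The same families as [dfe_spec()], but over the scaled effect
#' gamma = Tc * s, where Tc is the coalescence timescale. Scaled-space
#' surface theory consumes only this object. For the exponential beneficial
#' component, surface integrals against growing kernels exist only when
#' `gamma_b < 1`; larger values raise a divergence error at evaluation
#' time.
#'
#' @param family as in [dfe_spec()].
#' @param gamma_b,gamma_d scaled effect scales (dimensionless, > 0).
#' @param eta ratio Ub/Ud.
#' @param shape_b,shape_d gamma shapes.
#' @param table data.frame of atoms (column `s` interpreted as gamma).
#' @return an object of class `scaled_dfe`.
#' @export
scaled_dfe <- function(family = c("two_effect", "exponential_pair",
                                  "gamma_pair", "tabulated"),
                       gamma_b = NULL, gamma_d = NULL, eta = NULL,
                       shape_b = 1, shape_d = 1, table = NULL) {
  family <- match.arg(family)
  spec <- dfe_spec(family, sb = gamma_b, sd = gamma_d, eta = eta,
                   shape_b = shape_b, shape_d = shape_d, table = table)
  names(spec)[names(spec) == "sb"] <- "gamma_b"
  names(spec)[names(spec) == "sd"] <- "gamma_d"
  class(spec) <- "scaled_dfe"
  spec
}

#' Scale a DFE to the coalescence timescale
#'
#' Maps rho(s) to the distribution of scaled effects gamma = Tc * s.
#' Parametric scale parameters multiply by Tc; tabulated atoms map
#' pointwise. `unscale_dfe()` is the exact inverse.
#'
#' @param dfe a [dfe_spec()].
#' @param Tc coalescence timescale in generations (> 0).
#' @return a [scaled_dfe()].
#' @export
#' @examples
#' scale_dfe(dfe_spec("two_effect", sb = 1e-4, sd = 2e-4, eta = 1), 1e4)
scale_dfe <- function(dfe, Tc) {
  stopifnot(inherits(dfe, "dfe_spec"))
  if (!is.numeric(Tc) || Tc <= 0) stop("Tc must be positive")
  tab <- dfe$table
  if (!is.null(tab)) tab$s <- tab$s * Tc
  scaled_dfe(dfe$family,
             gamma_b = if (is.null(tab)) dfe$sb * Tc else NULL,
             gamma_d = if (is.null(tab)) dfe$sd * Tc else NULL,
             eta = if (is.null(tab)) dfe$eta else NULL,
             shape_b = dfe$shape_b, shape_d = dfe$shape_d, table = tab)
}

#' @rdname scale_dfe
#' @param sdfe a [scaled_dfe()].
#' @export
unscale_dfe <- function(sdfe, Tc) {
  stopifnot(inherits(sdfe, "scaled_dfe"))
  if (!is.numeric(Tc) || Tc <= 0) stop("Tc must be positive")
  tab <- sdfe$table
  if (!is.null(tab)) tab$s <- tab$s / Tc
  dfe_spec(sdfe$family,
           sb = if (is.null(tab)) sdfe$gamma_b / Tc else NULL,
           sd = if (is.null(tab)) sdfe$gamma_d / Tc else NULL,
           eta = if (is.null(tab)) sdfe$eta else NULL,
           shape_b = sdfe$shape_b, shape_d = sdfe$shape_d, table = tab)
}

#' @export
print.dfe_spec <- function(x, ...) {
  cat("DFE [", x$family, "]  sb =", format(x$sb), " sd =", format(x$sd),
      " eta =", format(x$eta), "\n")
  invisible(x)
}

#' @export
print.scaled_dfe <- function(x, ...) {
  cat("scaled DFE [", x$family, "]  gamma_b =", format(x$gamma_b),
      " gamma_d =", format(x$gamma_d), " eta =", format(x$eta), "\n")
  invisible(x)
}

.dfe_scales <- function(dfe) {
  if (inherits(dfe, "scaled_dfe")) list(sb = dfe$gamma_b, sd = dfe$gamma_d)
  else list(sb = dfe$sb, sd = dfe$sd)
}

stop_divergence <- function(msg) {
  stop(structure(class = c("ratchetwave_divergence", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# exp(x)-1)/x with a series branch against cancellation at small |x|
.expm1_over <- function(x) {
  small <- abs(x) < 1e-6
  out <- x
  out[small] <- 1 + x[small] / 2 + x[small]^2 / 6
  out[!small] <- expm1(x[!small]) / x[!small]
  out
}

# Normalised single-component tilted moments E[f(s) | component], where the
# beneficial component lives on s > 0 and the deleterious one on s < 0
# (scale parameters are magnitudes).  kind:
#   "exp"           f(s) = e^{a s}
#   "s_exp"         f(s) = s e^{a s}
#   "s2_exp"        f(s) = s^2 e^{a s}
#   "expm1_over_s"  f(s) = (e^{a s} - 1)/s
# Closed forms for point masses and exponentials; quadrature for gamma.
.component_moment <- function(family, scale, shape, table, kind, a, side,
                              method = "auto") {
  sgn <- if (side == "b") 1 else -1
  if (family == "tabulated") {
    keep <- if (side == "b") table$s > 0 else table$s < 0
    if (!any(keep)) return(0)
    s <- table$s[keep]; w <- table$weight[keep] / sum(table$weight[keep])
    f <- switch(kind,
                exp = exp(a * s),
                s_exp = s * exp(a * s),
                s2_exp = s^2 * exp(a * s),
                expm1_over_s = a * .expm1_over(a * s))
    return(sum(w * f))
  }
  if (family == "two_effect") {
    # point masses: the weighted sum is exact for every method

    s <- sgn * scale
    return(switch(kind,
                  exp = exp(a * s),
                  s_exp = s * exp(a * s),
                  s2_exp = s^2 * exp(a * s),
                  expm1_over_s = a * .expm1_over(a * s)))
  }
  # growing-kernel convergence: the tail of the beneficial density decays
  # like e^{-s/theta}; kernels carrying e^{a s} diverge when a >= 1/theta
  theta <- if (family == "gamma_pair") scale / shape else scale
  if (side == "b" && a > 0 && a * theta >= 1)
    stop_divergence(sprintf(
      "beneficial-tail integral diverges: a * scale = %.6g >= %g (kernel e^{a s} outpaces the e^{-s/theta} tail)",
      a * theta, 1))
  if (family == "exponential_pair" && method != "quadrature") {
    m <- scale
    am <- sgn * a * m   # tilt as seen from the magnitude axis
    return(switch(kind,
                  exp = 1 / (1 - am),
                  s_exp = sgn * m / (1 - am)^2,
                  s2_exp = 2 * m^2 / (1 - am)^3,
                  expm1_over_s = sgn * (-log1p(-am)) / m))
  }
  # numeric path: integrate over the magnitude t in (0, Inf); the tilted
  # density is assembled in log space so dens * e^{a s} never hits 0 * Inf
  th <- if (family == "gamma_pair") scale / shape else scale
  k <- if (family == "gamma_pair") shape else 1
  ldens <- function(t) (k - 1) * log(t) - t / th - lgamma(k) - k * log(th)
  integrand <- switch(kind,
    exp = function(t) exp(ldens(t) + a * sgn * t),
    s_exp = function(t) sgn * t * exp(ldens(t) + a * sgn * t),
    s2_exp = function(t) t^2 * exp(ldens(t) + a * sgn * t),
    expm1_over_s = function(t) {
      x <- a * sgn * t
      ifelse(x < 500, exp(ldens(t)) * a * .expm1_over(x),
             exp(ldens(t) + x) / (sgn * t))
    })
  # integrate in units of the tilted mean so mutation-scale (1e-4-ish)
  # mass is not lost in the (0, Inf) transformation; the tilt shifts the
  # effective scale to theta/(1 -+ a theta)
  th_eff <- th / (1 - sgn * a * th)
  if (th_eff <= 0) th_eff <- th   # a <= 0 tilts never flip sign here
  m_eff <- k * th_eff
  inner <- integrand
  integrand <- function(u) inner(m_eff * u) * m_eff
  if (k < 1) {
    # u = w^2 removes the integrable t^{k-1} singularity at the origin
    inner2 <- integrand
    integrand <- function(w) inner2(w^2) * 2 * w
  }
  val <- stats::integrate(integrand, 0, Inf,
                          rel.tol = 1e-11, abs.tol = 1e-13,
                          subdivisions = 500L)
  val$value
}

#' Weighted DFE integral
#'
#' Computes the mixture-weighted integral `\int rho(s) K(s) ds` that all
#' surface and rate formulas consume. Named kernels are parameterised by
#' the tilt `a` (equal to Tc for an unscaled DFE; use the default `a = 1`
#' for a [scaled_dfe()], whose argument is already gamma = Tc s):
#' \describe{
#'   \item{s_exp}{`s e^{a s}` (the rate-of-fitness-change kernel; scaled
#'     form gamma e^gamma).}
#'   \item{exp}{`e^{a s}` (fixation-rate kernel).}
#'   \item{exp_m1}{`e^{a s} - 1` (fixation-rate excess over neutral).}
#'   \item{s2_exp}{`s^2 e^{a s}` (the Airy fitness-scale kernel).}
#'   \item{expm1_over_s}{`(e^{a s} - 1)/s` (the implicit-Tc relation
#'     kernel), with a series branch near s = 0.}
#'   \item{alpha}{`e^{a s} - (e^{a s} - 1)/(a s)` rescaled by the tilt
#'     (the alpha = 0 kernel; scaled form e^gamma - (e^gamma - 1)/gamma,
#'     the fixation-rate kernel minus the sojourn/polymorphism kernel).}
#' }
#' A function `kernel(s)` is also accepted and is integrated by adaptive
#' quadrature (or summed over atoms for discrete families).
#'
#' Closed forms are used for the point-mass and exponential families;
#' gamma and tabulated families use quadrature / direct summation. A
#' divergence error (condition class `ratchetwave_divergence`) is raised
#' when the beneficial tail decays more slowly than the kernel grows
#' (e.g. exponential beneficial effects with `a * sb >= 1` under growing
#' kernels).
#'
#' @param dfe a [dfe_spec()] or [scaled_dfe()].
#' @param kernel kernel name (see Details) or a function of s.
#' @param a exponential tilt (use Tc for unscaled DFEs; must be 1 for
#'   scaled DFEs).
#' @param method `"auto"` (closed forms where available) or
#'   `"quadrature"` (force the numeric path; used as an independent
#'   cross-check).
#' @return the value of the integral.
#' @export
#' @examples
#' sdfe <- scaled_dfe("two_effect", gamma_b = 1, gamma_d = 1, eta = 1)
#' dfe_integral(sdfe, "s_exp")  # (e - 1/e)/2
dfe_integral <- function(dfe, kernel, a = 1, method = c("auto", "quadrature")) {
  method <- match.arg(method)
  if (inherits(dfe, "scaled_dfe") && !isTRUE(all.equal(a, 1)))
    stop("a scaled DFE is already in gamma units; use a = 1")
  if (is.function(kernel)) return(.dfe_integral_fn(dfe, kernel))
  kernel <- match.arg(kernel, c("s_exp", "exp", "exp_m1", "s2_exp",
                                "expm1_over_s", "alpha"))
  switch(kernel,
         exp_m1 = dfe_moment(dfe, "exp", a, method) - 1,
         alpha = dfe_moment(dfe, "exp", a, method) -
                 dfe_moment(dfe, "expm1_over_s", a, method) / a,
         dfe_moment(dfe, kernel, a, method))
}

#' @rdname dfe_integral
#' @param kind one of `"exp"`, `"s_exp"`, `"s2_exp"`, `"expm1_over_s"`.
#' @export
dfe_moment <- function(dfe, kind, a = 1, method = "auto") {
  sc <- .dfe_scales(dfe)
  if (dfe$family == "tabulated") {
    wb <- sum(dfe$table$weight[dfe$table$s > 0])
    wd <- sum(dfe$table$weight[dfe$table$s < 0])
    w0 <- sum(dfe$table$weight[dfe$table$s == 0])
    mb <- if (wb > 0) .component_moment(dfe$family, NA, NA, dfe$table, kind, a, "b", method) else 0
    md <- if (wd > 0) .component_moment(dfe$family, NA, NA, dfe$table, kind, a, "d", method) else 0
    f0 <- switch(kind, exp = 1, s_exp = 0, s2_exp = 0, expm1_over_s = a)
    return(wb * mb + wd * md + w0 * f0)
  }
  wb <- dfe$eta / (1 + dfe$eta)
  wd <- 1 / (1 + dfe$eta)
  mb <- if (wb > 0) .component_moment(dfe$family, sc$sb, dfe$shape_b, NULL,
                                      kind, a, "b", method) else 0
  md <- if (wd > 0) .component_moment(dfe$family, sc$sd, dfe$shape_d, NULL,
                                      kind, a, "d", method) else 0
  wb * mb + wd * md
}

# arbitrary-function kernel: quadrature over each side / sum over atoms
.dfe_integral_fn <- function(dfe, f) {
  sc <- .dfe_scales(dfe)
  if (dfe$family == "tabulated")
    return(sum(dfe$table$weight * vapply(dfe$table$s, f, 0)))
  wb <- dfe$eta / (1 + dfe$eta)
  wd <- 1 / (1 + dfe$eta)
  if (dfe$family == "two_effect")
    return(wb * f(sc$sb) + wd * f(-sc$sd))
  dens <- function(m, shape) {
    if (dfe$family == "gamma_pair")
      function(t) stats::dgamma(t, shape = shape, scale = m / shape)
    else function(t) stats::dexp(t, rate = 1 / m)
  }
  # integrate in units of the component mean (see .component_moment)
  side_int <- function(m, shape, sgn) {
    d <- dens(m, shape)
    stats::integrate(function(u) d(m * u) * vapply(sgn * m * u, f, 0) * m,
                     0, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  }
  ib <- if (wb > 0) side_int(sc$sb, dfe$shape_b, 1) else 0
  id <- if (wd > 0) side_int(sc$sd, dfe$shape_d, -1) else 0
  wb * ib + wd * id
}

# deleterious-component background-selection integral
# \int rho_d(|s|) (1 - e^{-a |s|})/|s| d|s|  (normalised over the
# deleterious component; equals the side-d "expm1_over_s" moment up to sign)
.ne_integral <- function(dfe, a) {
  sc <- .dfe_scales(dfe)
  if (dfe$family == "tabulated") {
    keep <- dfe$table$s < 0
    if (!any(keep)) return(0)
    t <- -dfe$table$s[keep]
    w <- dfe$table$weight[keep] / sum(dfe$table$weight[keep])
    return(sum(w * a * .expm1_over(-a * t)))
  }
  # (1 - e^{-a t})/t = -[(e^{-a t} - 1)/t] = -a * expm1_over(-a t)
  .component_moment(dfe$family, sc$sd, dfe$shape_d, NULL,
                    "expm1_over_s", a, "d")
}
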