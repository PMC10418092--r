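#' Airy function and its least negative zero
#'
#' `airy_ai()` evaluates the Airy function Ai(x) on the real line via its
#' Bessel-function representations (fractional-order `besselJ`/`besselK`).
#' `airy_zero()` returns the least negative zero z0 ~ -2.338, found by
#' root-finding on (-3, -2) and cached; it enters the fitness-lead scale
#' of the traveling-wave solution.
#'
#' @param x numeric vector.
#' @return `airy_ai()`: Ai(x); `airy_zero()`: the zero (scalar).
#' @export
#' @examples
#' airy_ai(airy_zero())  # ~ 0
airy_ai <- function(x) {
  vapply(x, function(xi) {
    if (xi < 0) {
      z <- 2 / 3 * abs(xi)^1.5
      sqrt(abs(xi)) / 3 * (besselJ(z, 1 / 3) + besselJ(z, -1 / 3))
    } else if (xi == 0) {
      3^(-2 / 3) / gamma(2 / 3)
    } else {
      z <- 2 / 3 * xi^1.5
      1 / pi * sqrt(xi / 3) * besselK(z, 1 / 3)
    }
  }, 0)
}

#' @rdname airy_ai
#' @export
airy_zero <- function() {
  if (is.null(.rw_cache$z0))
    .rw_cache$z0 <- stats::uniroot(airy_ai, c(-3, -2), tol = 1e-13)$root
  .rw_cache$z0
}

#' Fixation probabilities under linked selection
#'
#' `pfix_mssm()` is the moderate-selection strong-mutation (MSSM)
#' traveling-wave result `pfix(s) = e^{Tc s} / N`, valid for beneficial
#' and deleterious effects alike in rapidly evolving populations.
#' `pfix_diffusion()` is the classical single-locus diffusion formula
#' `(2 Tc / N) * 2 s / (1 - e^{-4 Tc s})` for independently evolving loci
#' (continuous at s = 0 with value 1/N). The two agree at s = 0 and
#' differ by a factor of two in the linear response to small Tc s.
#'
#' @param s fitness effect(s) (per generation; negative = deleterious).
#' @param Tc coalescence timescale (generations, > 0).
#' @param N census population size (>= 1).
#' @return fixation probability (vectorised over `s`).
#' @export
#' @examples
#' pfix_mssm(0, Tc = 100, N = 1e4)  # 1/N
pfix_mssm <- function(s, Tc, N) {
  stopifnot(Tc > 0, N >= 1)
  exp(Tc * s - log(N))
}

#' @rdname pfix_mssm
#' @export
pfix_diffusion <- function(s, Tc, N) {
  stopifnot(Tc > 0, N >= 1)
  out <- numeric(length(s))
  z <- 4 * Tc * s
  small <- abs(z) < 1e-10
  out[small] <- 1 / N
  out[!small] <- (2 * Tc / N) * 2 * s[!small] / (-expm1(-z[!small]))
  out
}

#' Rate of mean-fitness change and total fixation rate
#'
#' With `pfix(s) = e^{Tc s}/N`, the rate of change of mean fitness is
#' `v = N U \int rho(s) s pfix(s) ds = U \int rho(s) s e^{Tc s} ds`, and
#' the total selected fixation rate is `F = U \int rho(s) e^{Tc s} ds`.
#' `v_rate_diffusion()` evaluates v with the single-locus diffusion
#' fixation probability instead (used by the Ne-based heuristic branch of
#' unscaled surface curves).
#'
#' @param N census size; @param U total selected mutation rate per
#'   individual per generation; @param dfe a [dfe_spec()]; @param Tc
#'   coalescence timescale.
#' @return fitness change per generation (`v_rate`), fixations per
#'   generation (`fixation_rate`).
#' @export
v_rate <- function(N, U, dfe, Tc) {
  U * dfe_moment(dfe, "s_exp", a = Tc)
}

#' @rdname v_rate
#' @export
fixation_rate <- function(N, U, dfe, Tc) {
  U * dfe_moment(dfe, "exp", a = Tc)
}

#' @rdname v_rate
#' @export
v_rate_diffusion <- function(N, U, dfe, Tc) {
  N * U * .dfe_integral_fn(dfe, function(s) s * pfix_diffusion(s, Tc, N))
}

# the implicit relation g(Tc) = 0 fixing Tc; all self-consistent pieces
.mssm_pieces <- function(Tc, N, U, dfe) {
  z0 <- airy_zero()
  Ms <- dfe_moment(dfe, "s_exp", a = Tc)
  Me <- dfe_moment(dfe, "exp", a = Tc)
  M2 <- dfe_moment(dfe, "s2_exp", a = Tc)
  Mf <- dfe_moment(dfe, "expm1_over_s", a = Tc)
  v <- U * Ms
  b <- (U / 2 * M2)^(1 / 3)
  xc <- U * (Tc * Ms + 1 - Me) - b * z0 - 1 / Tc
  g <- if (xc > 0) {
    val <- Tc * (xc - U) - v * Tc^2 / 2 + U * Mf - log(N * xc)
    if (is.finite(val)) val else NA_real_
  } else NA_real_
  list(g = g, v = v, b = b, xc = xc, F = U * Me, z0 = z0)
}

#' Solve the implicit MSSM relation for the coalescence timescale
#'
#' The coalescence timescale Tc (~ half the mean pairwise coalescent
#' time) is fixed by the population parameters through the implicit
#' traveling-wave relation
#' `log(N xc) = Tc (xc - U) - v Tc^2 / 2 + U \int rho(s) (e^{Tc s}-1)/s ds`,
#' with the fitness-lead scale
#' `xc = U \int rho(s) [Tc s e^{Tc s} + 1 - e^{Tc s}] ds - b z0 - 1/Tc`
#' and the Airy fitness scale `b^3 = (U/2) \int rho(s) s^2 e^{Tc s} ds`,
#' where z0 is the least negative Airy zero and v is evaluated
#' self-consistently at the same Tc. The solver scans g(Tc) on a log grid
#' over (0, ~10 N], bisects every bracketed sign change, and returns the
#' root with the best validity diagnostics (all roots are reported).
#'
#' Validity of the approximation requires Tc * Dxf >> 1 (with Dxf ~ b)
#' and typical fixed effects small compared to Dxf, plus Tc * Ub >> 1; a
#' warning (never an error) is emitted when Tc * Ub < 1 or Tc * b < 2.
#'
#' @inheritParams v_rate
#' @param bracket optional Tc search interval; default `c(1, 10 N)`.
#' @param n_scan number of log-grid scan points.
#' @param quiet suppress validity warnings.
#' @return an object of class `mssm_solution`: list with `Tc`, `xc`, `b`,
#'   `v`, `F` (total selected fixation rate), `z0`, `residual`,
#'   `all_roots`, and a `validity` record.
#' @export
solve_Tc <- function(N, U, dfe, bracket = NULL, n_scan = 400, quiet = FALSE) {
  stopifnot(N > 0, U > 0)
  if (is.null(bracket)) bracket <- c(1, 10 * N)
  g <- function(Tc) .mssm_pieces(Tc, N, U, dfe)$g
  Tcs <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_scan))
  gs <- vapply(Tcs, function(tc) tryCatch(g(tc), error = function(e) NA_real_), 0)
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1)) {
    if (!is.na(gs[i]) && !is.na(gs[i + 1]) &&
        sign(gs[i]) != sign(gs[i + 1])) {
      r <- tryCatch(
        stats::uniroot(g, c(Tcs[i], Tcs[i + 1]), tol = 1e-12)$root,
        error = function(e) NA_real_)
      if (!is.na(r)) roots <- c(roots, r)
    }
  }
  if (!length(roots)) {
    sgn <- unique(sign(gs[!is.na(gs)]))
    stop("no root of the Tc relation in the bracket [",
         format(bracket[1]), ", ", format(bracket[2]),
         "]; residual sign pattern: ",
         if (!length(sgn)) "undefined (xc <= 0 throughout)"
         else paste(sgn, collapse = ","))
  }
  eta <- dfe$eta
  Ub <- U * eta / (1 + eta)
  # pick the root whose validity diagnostics are best (largest rapid-
  # evolution margin); with a single sign change this is the neutral-end
  # root near Tc ~ N
  score <- vapply(roots, function(r) {
    p <- .mssm_pieces(r, N, U, dfe)
    min(r * p$b, if (Ub > 0) r * Ub else Inf)
  }, 0)
  Tc <- roots[which.max(score)]
  p <- .mssm_pieces(Tc, N, U, dfe)
  s_tilde_b <- if (eta > 0) {
    mb <- .component_moment(dfe$family, .dfe_scales(dfe)$sb, dfe$shape_b,
                            dfe$table, "s_exp", Tc, "b") /
          .component_moment(dfe$family, .dfe_scales(dfe)$sb, dfe$shape_b,
                            dfe$table, "exp", Tc, "b")
    mb
  } else NA_real_
  s_tilde_d <- abs(.component_moment(dfe$family, .dfe_scales(dfe)$sd,
                                     dfe$shape_d, dfe$table, "s_exp", Tc, "d") /
                   .component_moment(dfe$family, .dfe_scales(dfe)$sd,
                                     dfe$shape_d, dfe$table, "exp", Tc, "d"))
  validity <- list(Tc_dxf = Tc * p$b, Tc_Ub = Tc * Ub,
                   s_tilde_b = s_tilde_b, s_tilde_d = s_tilde_d,
                   s_tilde_b_over_dxf = s_tilde_b / p$b,
                   s_tilde_d_over_dxf = s_tilde_d / p$b)
  if (!quiet) {
    if (Ub > 0 && Tc * Ub < 1)
      warning("MSSM validity: Tc * Ub = ", signif(Tc * Ub, 3),
              " < 1 (beneficial mutations too rare per coalescence time)",
              call. = FALSE)
    if (Tc * p$b < 2)
      warning("MSSM validity: Tc * b = ", signif(Tc * p$b, 3),
              " < 2 (population not clearly in the rapid-evolution regime)",
              call. = FALSE)
  }
  structure(list(Tc = Tc, xc = p$xc, b = p$b, v = p$v, F = p$F,
                 z0 = p$z0, residual = p$g, all_roots = sort(roots),
                 validity = validity, N = N, U = U, dfe = dfe),
            class = "mssm_solution")
}

#' @export
print.mssm_solution <- function(x, ...) {
  cat("MSSM solution:  Tc =", format(x$Tc), " (residual",
      format(x$residual, digits = 3), ")\n")
  cat("  xc =", format(x$xc), "  b =", format(x$b),
      "  z0 =", format(x$z0), "\n")
  cat("  v =", format(x$v), "  F =", format(x$F), "\n")
  cat("  validity: Tc*b =", format(x$validity$Tc_dxf, digits = 4),
      "  Tc*Ub =", format(x$validity$Tc_Ub, digits = 4), "\n")
  if (length(x$all_roots) > 1)
    cat("  (", length(x$all_roots), "roots found:",
        paste(signif(x$all_roots, 5), collapse = ", "), ")\n")
  invisible(x)
}

#' Background-selection (Ne-based) coalescence heuristic
#'
#' When deleterious effects are strong, the coalescence timescale is set
#' by the classic background-selection reduction: Tc is the fixed point
#' of `Tc = N exp(-Ud \int rho_d(s) (1 - e^{-Tc s})/s ds)` (the integral
#' runs over the deleterious component only; beneficial mutations are
#' neglected here). With a single deleterious effect and Tc sd >> 1 this
#' reduces to the familiar `N e^{-Ud/sd}`. Solved by damped fixed-point
#' iteration on log Tc.
#'
#' @param N census population size.
#' @param Ud deleterious mutation rate per individual per generation.
#' @param dfe a [dfe_spec()]; only its deleterious component is used.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap (non-convergence is an error).
#' @return Tc (generations).
#' @export
#' @examples
#' d <- dfe_spec("two_effect", sb = 1e-3, sd = 0.02, eta = 0)
#' tc_ne_heuristic(1e5, 0.05, d)  # ~ 1e5 * exp(-0.05/0.02)
tc_ne_heuristic <- function(N, Ud, dfe, tol = 1e-12, max_iter = 1000) {
  stopifnot(N > 0, Ud >= 0)
  if (Ud == 0) return(N)
  logTc <- log(N)
  for (i in seq_len(max_iter)) {
    new <- log(N) - Ud * .ne_integral(dfe, exp(logTc))
    new <- 0.5 * logTc + 0.5 * new   # damping
    if (abs(new - logTc) < tol * max(1, abs(logTc))) {
      Tc <- exp(new)
      resid <- abs(Tc - N * exp(-Ud * .ne_integral(dfe, Tc))) / Tc
      if (resid > 1e-10)
        stop("fixed-point iteration converged poorly (residual ", resid, ")")
      return(Tc)
    }
    logTc <- new
  }
  stop("tc_ne_heuristic did not converge after ", max_iter,
       " iterations (pathological parameters?)")
}

#' Critical census population size
#'
#' For a fixed mutation rate and DFE, the rate of fitness change v
#' crosses zero at a critical census size N0: populations larger than N0
#' adapt, smaller ones decline (the mutational-meltdown boundary). Found
#' by nesting [solve_Tc()] in a bracketed root search over log N.
#'
#' @param U total selected mutation rate; @param dfe a [dfe_spec()].
#' @param bracket census-size search interval.
#' @return N0, with v(N0) = 0.
#' @export
critical_population_size <- function(U, dfe, bracket = c(1e2, 1e12)) {
  vN <- function(logN) {
    solve_Tc(exp(logN), U, dfe, quiet = TRUE)$v
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  vlo <- vN(lo); vhi <- vN(hi)
  if (sign(vlo) == sign(vhi))
    stop("v has the same sign (", sign(vlo), ") at both bracket ends; ",
         "no v = 0 crossing for this DFE in [", format(bracket[1]), ", ",
         format(bracket[2]), "]")
  exp(stats::uniroot(vN, c(lo, hi), tol = 1e-10)$root)
}
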