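#' Fitness-mediated epistasis rules
#'
#' A rule describing how the available beneficial and deleterious effect
#' magnitudes depend on an individual's log-fitness X (relative to the
#' founding genotype, X = 0 at initialisation):
#' \describe{
#'   \item{diminishing_returns}{`sb(X) = sb0 e^{-X/L}`, sd constant -
#'     beneficial effects weaken on fitter backgrounds.}
#'   \item{increasing_costs}{`sd(X) = sd0 e^{+X/L}`, sb constant -
#'     deleterious effects strengthen on fitter backgrounds.}
#'   \item{decreasing_costs}{`sd(X) = sd0 e^{-X/L}`, sb constant.}
#'   \item{dr_plus_ic}{both: `sb(X) = sb0 e^{-X/L}`,
#'     `sd(X) = sd0 e^{+X/L}`; the product sb*sd is exactly conserved.}
#'   \item{custom}{user functions `fb(X)`, `fd(X)` returning the scales.}
#' }
#' The fitness length-scale `L` defaults to 5 (in log-fitness units).
#'
#' @param pattern one of the patterns above.
#' @param sb0,sd0 effect scales at X = 0.
#' @param length_scale L, the fitness scale of the exponential
#'   dependence.
#' @param fb,fd functions of X (only for `pattern = "custom"`).
#' @return an object of class `epistasis_rule`.
#' @export
epistasis_rule <- function(pattern = c("diminishing_returns",
                                       "increasing_costs",
                                       "decreasing_costs", "dr_plus_ic",
                                       "custom"),
                           sb0, sd0, length_scale = 5,
                           fb = NULL, fd = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(sb0 > 0, sd0 > 0, length_scale > 0)
  if (pattern == "custom" && (is.null(fb) || is.null(fd)))
    stop("custom pattern requires functions fb(X) and fd(X)")
  structure(list(pattern = pattern, sb0 = sb0, sd0 = sd0,
                 length_scale = length_scale, fb = fb, fd = fd),
            class = "epistasis_rule")
}

#' Effect magnitudes on a given fitness background
#'
#' Evaluates an [epistasis_rule()] at log-fitness X. For `dr_plus_ic`
#' the product `sb * sd = sb0 * sd0` is conserved exactly for every X.
#'
#' @param rule an [epistasis_rule()].
#' @param X log-fitness (vectorised).
#' @return list with components `sb` and `sd` (same length as X).
#' @export
#' @examples
#' r <- epistasis_rule("dr_plus_ic", sb0 = 0.01, sd0 = 0.01)
#' effect_update(r, X = 5)  # (sb0/e, sd0*e)
effect_update <- function(rule, X) {
  stopifnot(inherits(rule, "epistasis_rule"))
  L <- rule$length_scale
  switch(rule$pattern,
    diminishing_returns = list(sb = rule$sb0 * exp(-X / L),
                               sd = rep(rule$sd0, length(X))),
    increasing_costs = list(sb = rep(rule$sb0, length(X)),
                            sd = rule$sd0 * exp(X / L)),
    decreasing_costs = list(sb = rep(rule$sb0, length(X)),
                            sd = rule$sd0 * exp(-X / L)),
    dr_plus_ic = list(sb = rule$sb0 * exp(-X / L),
                      sd = rule$sd0 * exp(X / L)),
    custom = list(sb = vapply(X, rule$fb, 0), sd = vapply(X, rule$fd, 0)))
}

.epistasis_code <- function(pattern) {
  switch(pattern, diminishing_returns = 1L, increasing_costs = 2L,
         decreasing_costs = 3L, dr_plus_ic = 4L,
         stop("pattern '", pattern,
              "' is not supported by the individual-based simulator"))
}

#' Individual-based simulation under fitness-mediated epistasis
#'
#' Identical dynamics to [run_generations()], except that the effect
#' magnitudes available to each individual depend on that individual's
#' own current log-fitness through the [epistasis_rule()] - the next
#' available mutation is updated after each mutation event. Runs for
#' `generations` generations (default 5000) recording mean fitness,
#' fixed-mutation counts and heterozygosities every `record_every`
#' generations (default 100). With `length_scale = Inf` the dynamics
#' reduce bitwise to the fixed-DFE simulator under the same seed.
#'
#' @param pop a [wf_population()] whose DFE family is `two_effect` (its
#'   sb/sd are ignored; the rule's sb0/sd0 apply at X = 0).
#' @param rule an [epistasis_rule()] (parametric patterns only).
#' @param generations,record_every run length and recording cadence.
#' @return an object of class `epistasis_trajectory`: data.frame
#'   (generation, mean_fitness, fixed_sel, fixed_neu, pi_neu, pi_sel,
#'   sb, sd) with attributes `classification`, `rule`, `population`.
#'   sb/sd columns give the effect scales at the recorded mean fitness.
#' @export
simulate_epistatic <- function(pop, rule, generations = 5000,
                               record_every = 100) {
  stopifnot(inherits(pop, "wf_population"), inherits(rule, "epistasis_rule"))
  if (pop$dfe$family != "two_effect")
    stop("fitness-dependent effects are supported for the two_effect family")
  pop <- .wf_chunk(pop, generations, record_every = record_every,
                   epistasis = .epistasis_code(rule$pattern),
                   sb0 = rule$sb0, sd0 = rule$sd0,
                   length_scale = rule$length_scale)
  traj <- attr(pop, "last_chunk")$trajectory
  eff <- effect_update(rule, traj$mean_fitness)
  traj$sb <- eff$sb
  traj$sd <- eff$sd
  # classify from epoch-scale slopes of the fitness trajectory
  n <- nrow(traj)
  third <- max(2L, floor(n / 3))
  slope <- function(d) unname(stats::coef(stats::lm(mean_fitness ~
                                                      generation, d))[2])
  v_early <- slope(traj[seq_len(third), ])
  v_late <- slope(traj[seq.int(n - third + 1L, n), ])
  cls <- if (abs(v_late) <= 0.1 * abs(v_early)) "approaches_v0"
         else if (v_late > 0) "adapts_indefinitely" else "declines"
  structure(traj, classification = cls, v_early = v_early, v_late = v_late,
            rule = rule, population = pop,
            class = c("epistasis_trajectory", "data.frame"))
}

#' Slow-epistasis theory flow through parameter space
#'
#' Under the slow-epistasis assumption, the DFE shifts with the
#' population's mean fitness much more slowly than the population
#' equilibrates, so at every instant the rate of fitness change is the
#' steady-state v for the current DFE. The flow `dX/dt = v(N, U,
#' rho(.|X))` is integrated by adaptive explicit Euler, re-solving the
#' coalescence timescale as the DFE shifts; the step is limited so the
#' per-step change of the effect scales stays below 1%. Integration
#' terminates at the horizon or at a fixed point (|v| below `v_tol`,
#' default 1e-3 of the initial |v|).
#'
#' @param N,U,eta population-genetic parameters.
#' @param rule an [epistasis_rule()].
#' @param X0 initial log-fitness.
#' @param horizon time horizon in generations.
#' @param v_tol fixed-point tolerance on |v|.
#' @param family DFE family for the instantaneous DFE.
#' @return data.frame path (t, X, sb, sd, Nsb, Nsd, v, Tc) with
#'   attributes `terminated` (`"fixed_point"`, `"horizon"` or
#'   `"solver_failure"`) and `classification`.
#' @export
theory_flow <- function(N, U, eta, rule, X0 = 0, horizon = 5000,
                        v_tol = NULL, family = "two_effect") {
  stopifnot(inherits(rule, "epistasis_rule"))
  L <- rule$length_scale
  state_row <- function(t, X) {
    eff <- effect_update(rule, X)
    dfe <- dfe_spec(family, sb = eff$sb, sd = eff$sd, eta = eta)
    sol <- solve_Tc(N, U, dfe, quiet = TRUE)
    data.frame(t = t, X = X, sb = eff$sb, sd = eff$sd,
               Nsb = N * eff$sb, Nsd = N * eff$sd, v = sol$v, Tc = sol$Tc)
  }
  path <- list()
  row <- tryCatch(state_row(0, X0), error = function(e) NULL)
  if (is.null(row)) stop("Tc solver failed at the initial condition")
  if (is.null(v_tol)) v_tol <- 1e-3 * abs(row$v)
  path[[1]] <- row
  terminated <- "horizon"
  t <- 0
  while (t < horizon) {
    v <- row$v
    if (abs(v) < v_tol) {
      terminated <- "fixed_point"
      break
    }
    # |dX| <= 0.01 L keeps per-step changes in sb, sd below ~1%
    dt <- min(horizon - t, 0.01 * L / abs(v))
    nxt <- NULL
    repeat {
      Xn <- row$X + v * dt
      nxt <- tryCatch(state_row(t + dt, Xn), error = function(e) NULL)
      # halve the step rather than overshoot the v = 0 crossing
      if (!is.null(nxt) && sign(nxt$v) != sign(v) &&
          abs(nxt$v) > v_tol && dt > 1e-6 * L / abs(v)) {
        dt <- dt / 2
      } else break
    }
    if (is.null(nxt)) {
      terminated <- "solver_failure"
      break
    }
    t <- t + dt
    row <- nxt
    path[[length(path) + 1]] <- row
  }
  out <- do.call(rbind, path)
  cls <- if (terminated == "fixed_point") "approaches_v0"
         else if (out$v[nrow(out)] > 0) "adapts_indefinitely" else "declines"
  structure(out, terminated = terminated, classification = cls)
}

#' Long-term fixed points along an epistatic constraint line
#'
#' Under diminishing-returns epistasis a population is constrained to a
#' horizontal line (fixed Nsd) in the (Nsd, Nsb) plane; under
#' increasing- or decreasing-costs epistasis to a vertical line (fixed
#' Nsb). Intersections of the constraint line with the v=0 curve are the
#' long-term fixed points, and stability follows from the sign of v on
#' either side combined with the direction of motion the pattern
#' implies: v > 0 above the curve; diminishing returns moves Nsb
#' downward when v > 0; increasing costs moves Nsd rightward when
#' v > 0; decreasing costs moves it leftward (so the stabilities of the
#' two crossings are swapped relative to increasing costs). A vertical
#' line with Nsb above the curve's extremal Nsb* has no intersection:
#' no long-term attractor exists.
#'
#' @param pattern epistasis pattern name.
#' @param line_spec list with `Nsd` (horizontal line) or `Nsb`
#'   (vertical line).
#' @param v0_curve a [v0_curve()] result.
#' @return data.frame (Nsd, Nsb, stability); zero rows when the line
#'   does not intersect the curve.
#' @export
classify_fixed_points <- function(pattern, line_spec, v0_curve) {
  stopifnot(inherits(v0_curve, "surface_curve"), v0_curve$surface == "v0")
  pts <- v0_curve$points[!is.na(v0_curve$points$Nsb), ]
  if (nrow(pts) < 2) stop("v0 curve has too few resolved points")
  empty <- data.frame(Nsd = numeric(0), Nsb = numeric(0),
                      stability = character(0))
  # v > 0 strictly above the curve, v < 0 strictly below
  if (pattern == "diminishing_returns") {
    nsd0 <- line_spec$Nsd
    if (nsd0 < min(pts$Nsd) || nsd0 > max(pts$Nsd)) return(empty)
    nsb0 <- stats::approx(pts$Nsd, pts$Nsb, xout = nsd0)$y
    # motion: dNsb/dt has sign -v; above the curve v>0 pushes down,
    # below v<0 pushes up: always attracting
    return(data.frame(Nsd = nsd0, Nsb = nsb0, stability = "stable"))
  }
  if (!pattern %in% c("increasing_costs", "decreasing_costs"))
    stop("constraint-line classification applies to diminishing_returns, ",
         "increasing_costs and decreasing_costs patterns")
  nsb0 <- line_spec$Nsb
  d <- pts$Nsb - nsb0
  cross <- which(d[-1] * d[-length(d)] < 0)
  if (!length(cross)) return(empty)
  fps <- vapply(cross, function(i) {
    stats::approx(pts$Nsb[c(i, i + 1)], pts$Nsd[c(i, i + 1)], xout = nsb0)$y
  }, 0)
  fps <- sort(fps)
  # v sign along the vertical line just left/right of each crossing;
  # motion dNsd/dt = +sign(v) (increasing costs) or -sign(v) (decreasing)
  motion_sign <- if (pattern == "increasing_costs") 1 else -1
  v_sign_at <- function(nsd) {
    curve_nsb <- stats::approx(pts$Nsd, pts$Nsb, xout = nsd, rule = 2)$y
    if (nsb0 > curve_nsb) 1 else -1
  }
  stab <- vapply(seq_along(fps), function(k) {
    eps <- 0.02 * fps[k]
    move_left <- motion_sign * v_sign_at(fps[k] - eps)   # +1 -> rightward
    move_right <- motion_sign * v_sign_at(fps[k] + eps)
    if (move_left >= 0 && move_right <= 0) "stable" else "unstable"
  }, "")
  data.frame(Nsd = fps, Nsb = nsb0, stability = stab)
}
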