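.family_code <- function(family) {
  match(family, c("two_effect", "exponential_pair", "gamma_pair",
                  "tabulated")) - 1L
}

.wf_params <- function(pop, epistasis = 0L, sb0 = 0, sd0 = 0,
                       length_scale = Inf) {
  dfe <- pop$dfe
  list(U = pop$U, Un = pop$Un, family = .family_code(dfe$family),
       sb = if (is.null(dfe$sb) || is.na(dfe$sb)) 0 else dfe$sb,
       sd = if (is.null(dfe$sd) || is.na(dfe$sd)) 0 else dfe$sd,
       shape_b = dfe$shape_b, shape_d = dfe$shape_d,
       eta = if (is.finite(dfe$eta)) dfe$eta else 1e12,
       tab_s = if (!is.null(dfe$table)) dfe$table$s else numeric(0),
       tab_w = if (!is.null(dfe$table)) dfe$table$weight else numeric(0),
       epistasis = as.integer(epistasis), sb0 = sb0, sd0 = sd0,
       length_scale = if (is.finite(length_scale)) length_scale else 1e18)
}

#' Create a Wright-Fisher population
#'
#' Initialises a clonal haploid population of `N` individuals for
#' individual-based forward simulation. Each generation consists of a
#' mutation step - every individual acquires Poisson(`U`) selected
#' mutations with effects drawn from the DFE, plus Poisson(`Un`) purely
#' neutral mutations - and a reproduction step in which individuals are
#' resampled with replacement with probabilities proportional to e^X
#' (computed as e^{X - max X} for stability), X being log-fitness. The
#' genome is infinite-sites: every mutation event is a new tracked
#' record; there is no back-mutation or recombination. Fixed mutations
#' are compacted out of genotypes into a fixed ledger.
#'
#' @param N population size (constant every generation).
#' @param U selected mutation rate per individual per generation.
#' @param Un neutral mutation rate per individual per generation
#'   (default 0.01).
#' @param dfe a [dfe_spec()].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   so the run is bit-reproducible.
#' @return an object of class `wf_population`.
#' @export
wf_population <- function(N, U, Un = 0.01, dfe, seed = NULL) {
  stopifnot(N >= 1, U >= 0, Un >= 0, inherits(dfe, "dfe_spec"))
  if (!is.null(seed)) set.seed(seed)
  empty <- lapply(seq_len(N), function(i) integer(0))
  structure(list(
    N = as.integer(N), U = U, Un = Un, dfe = dfe,
    genomes_sel = empty, genomes_neu = empty, X = numeric(N),
    generation = 0L, next_id = 1L,
    active = data.frame(id = integer(0), effect = numeric(0),
                        neutral = logical(0), origin = integer(0)),
    fixed = data.frame(id = integer(0), effect = numeric(0),
                       neutral = logical(0), generation = integer(0)),
    lost = data.frame(id = integer(0), neutral = logical(0),
                      generation = integer(0)),
    seed = seed), class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  cat("Wright-Fisher population: N =", x$N, " U =", x$U, " Un =", x$Un,
      "\n  generation", x$generation, ";", nrow(x$active),
      "segregating,", nrow(x$fixed), "fixed (",
      sum(!x$fixed$neutral), "selected )\n  mean fitness",
      format(mean(x$X), digits = 6), "\n")
  invisible(x)
}

# low-level chunk runner shared by all simulation entry points
.wf_chunk <- function(pop, generations, stop_at_first_fixation = FALSE,
                      record_every = 0L, epistasis = 0L, sb0 = 0, sd0 = 0,
                      length_scale = Inf) {
  res <- .wf_run_cpp(pop$genomes_sel, pop$genomes_neu, pop$X,
                     pop$active$id, pop$active$effect, pop$active$neutral,
                     pop$active$origin, pop$next_id, pop$generation,
                     .wf_params(pop, epistasis, sb0, sd0, length_scale),
                     as.integer(generations), stop_at_first_fixation,
                     as.integer(record_every))
  pop$genomes_sel <- res$genomes_sel
  pop$genomes_neu <- res$genomes_neu
  pop$X <- res$X
  pop$generation <- res$generation
  pop$next_id <- res$next_id
  pop$active <- data.frame(id = res$active_id, effect = res$active_effect,
                           neutral = res$active_neutral,
                           origin = res$active_origin)
  pop$fixed <- rbind(pop$fixed, res$fixed)
  pop$lost <- rbind(pop$lost, res$lost)
  attr(pop, "last_chunk") <- res[c("trajectory", "first_fix_gen",
                                   "mean_fitness", "pi_neu", "pi_sel")]
  pop
}

#' Advance a population
#'
#' `generation_step()` performs exactly one mutation + reproduction
#' cycle; `run_generations()` advances by `generations` cycles and
#' optionally records a trajectory.
#'
#' @param pop a [wf_population()].
#' @param generations number of generations to advance.
#' @param record_every record mean fitness, heterozygosities and
#'   cumulative fixation counts every this many generations (0 = none).
#' @return the advanced population; `run_generations()` attaches the
#'   recorded trajectory as `attr(pop, "last_chunk")$trajectory`.
#' @export
generation_step <- function(pop) {
  run_generations(pop, 1L)
}

#' @rdname generation_step
#' @export
run_generations <- function(pop, generations, record_every = 0L) {
  stopifnot(inherits(pop, "wf_population"))
  .wf_chunk(pop, generations, record_every = record_every)
}

#' Epoch protocol
#'
#' Runs the standard measurement protocol: from a clonal start, the
#' number of generations until the first fixation of any mutation sets
#' the *epoch length*; the run then proceeds in epochs of that length
#' (up to `max_epochs`), recording mean fitness, neutral and selected
#' pairwise heterozygosity, and cumulative fixation counts at each epoch
#' boundary. If no mutation fixes within `first_fix_cap` generations the
#' run is flagged (`cap_exceeded`) rather than discarded.
#'
#' @param pop a clonal [wf_population()] (generation 0).
#' @param max_epochs maximum number of epochs (default 100).
#' @param first_fix_cap generations allowed for the first fixation.
#' @param total_gen_cap overall generation budget; exceeded = flagged.
#' @return an object of class `epoch_reports`: data.frame with one row
#'   per epoch (epoch, generation, mean_fitness, pi_neu, pi_sel,
#'   fixed_sel, fixed_neu, fixed_effect_sum) with attributes
#'   `epoch_length`, `cap_exceeded`, `population`.
#' @export
run_epochs <- function(pop, max_epochs = 100, first_fix_cap = 1e5,
                       total_gen_cap = 1e5) {
  stopifnot(inherits(pop, "wf_population"))
  if (pop$generation != 0L)
    stop("epoch protocol requires a clonally initialised population")
  pop <- .wf_chunk(pop, first_fix_cap, stop_at_first_fixation = TRUE)
  ffg <- attr(pop, "last_chunk")$first_fix_gen
  if (ffg < 0) {
    rep0 <- data.frame(epoch = integer(0), generation = integer(0),
                       mean_fitness = numeric(0), pi_neu = numeric(0),
                       pi_sel = numeric(0), fixed_sel = integer(0),
                       fixed_neu = integer(0), fixed_effect_sum = numeric(0))
    return(structure(rep0, epoch_length = NA_integer_, cap_exceeded = TRUE,
                     population = pop, class = c("epoch_reports",
                                                 "data.frame")))
  }
  epoch_length <- ffg
  reports <- list()
  report_row <- function(epoch, pop) {
    lc <- attr(pop, "last_chunk")
    sel <- !pop$fixed$neutral
    data.frame(epoch = epoch, generation = pop$generation,
               mean_fitness = lc$mean_fitness, pi_neu = lc$pi_neu,
               pi_sel = lc$pi_sel, fixed_sel = sum(sel),
               fixed_neu = sum(!sel),
               fixed_effect_sum = sum(pop$fixed$effect[sel]))
  }
  reports[[1]] <- report_row(1L, pop)
  capped <- FALSE
  n_ep <- 1L
  while (n_ep < max_epochs) {
    if (pop$generation + epoch_length > total_gen_cap) {
      capped <- TRUE
      break
    }
    pop <- .wf_chunk(pop, epoch_length)
    n_ep <- n_ep + 1L
    reports[[n_ep]] <- report_row(n_ep, pop)
  }
  out <- do.call(rbind, reports)
  structure(out, epoch_length = epoch_length, cap_exceeded = capped,
            population = pop, class = c("epoch_reports", "data.frame"))
}

#' Pairwise heterozygosity
#'
#' The average number of polymorphisms by which two randomly sampled
#' individuals differ, restricted to neutral or selected mutations.
#' Computed exactly from carrier counts: a mutation carried by c of N
#' individuals contributes 2 c (N - c) / (N (N - 1)) - the all-pairs
#' average of the symmetric-difference count.
#'
#' @param pop a [wf_population()] with at least 2 individuals.
#' @param class `"neutral"` or `"selected"`.
#' @return pi (non-negative scalar).
#' @export
measure_heterozygosity <- function(pop, class = c("neutral", "selected")) {
  class <- match.arg(class)
  stopifnot(inherits(pop, "wf_population"), pop$N >= 2)
  genomes <- if (class == "neutral") pop$genomes_neu else pop$genomes_sel
  ids <- unlist(genomes)
  if (!length(ids)) return(0)
  counts <- table(ids)
  N <- pop$N
  sum(2 * counts * (N - counts)) / (N * (N - 1))
}

#' Measured evolutionary rates
#'
#' Summarises an epoch run: `v_hat` is the least-squares slope of mean
#' fitness against generation at epoch resolution; `F_hat` is the number
#' of selected fixations per generation; `Tc_hat` is the coalescence
#' timescale estimated from run-averaged neutral heterozygosity as
#' pi_neu / (4 Un) (the second half of the epochs is used, discarding
#' the equilibration from the clonal start).
#'
#' @param reports an `epoch_reports` object from [run_epochs()].
#' @param Un the neutral mutation rate used in the run (defaults to the
#'   rate stored in the report's population).
#' @param burn_frac initial fraction of epochs discarded for `Tc_hat`.
#' @return list with `v_hat`, `F_hat`, `Tc_hat`, `pi_neu`, `pi_sel`,
#'   `n_epochs`, `total_generations`.
#' @export
measured_rates <- function(reports, Un = NULL, burn_frac = 0.5) {
  stopifnot(inherits(reports, "epoch_reports"))
  if (is.null(Un)) Un <- attr(reports, "population")$Un
  n <- nrow(reports)
  if (n < 10)
    warning("fewer than 10 epochs (", n, "); estimates are unreliable",
            call. = FALSE)
  if (n < 2)
    return(list(v_hat = NA_real_, F_hat = NA_real_, Tc_hat = NA_real_,
                pi_neu = NA_real_, pi_sel = NA_real_, n_epochs = n,
                total_generations = if (n) reports$generation[n] else 0))
  v_hat <- unname(stats::coef(stats::lm(mean_fitness ~ generation,
                                        data = reports))[2])
  total_gen <- reports$generation[n]
  F_hat <- reports$fixed_sel[n] / total_gen
  late <- reports[seq.int(max(1, floor(n * burn_frac) + 1), n), ]
  pi_neu <- mean(late$pi_neu)
  pi_sel <- mean(late$pi_sel)
  Tc_hat <- if (Un > 0) pi_neu / (4 * Un) else NA_real_
  list(v_hat = v_hat, F_hat = F_hat, Tc_hat = Tc_hat, pi_neu = pi_neu,
       pi_sel = pi_sel, n_epochs = n, total_generations = total_gen)
}

#' McDonald-Kreitman-like alpha statistic
#'
#' `alpha = 1 - (Un * pi_sel) / (F * pi_neu)`: a contrast of selected
#' vs neutral polymorphism against selected vs neutral divergence.
#' alpha = 0 mimics neutrality; alpha < 0 indicates that purifying
#' selection dominates the polymorphism signal (as on the v=0 surface);
#' alpha > 0 indicates adaptive divergence.
#'
#' @param Un neutral mutation rate; @param pi_sel,pi_neu heterozygosities
#'   of selected / neutral mutations; @param F selected fixation rate per
#'   generation (> 0).
#' @return alpha (<= 1).
#' @export
alpha_stat <- function(Un, pi_sel, pi_neu, F) {
  if (is.na(F) || F <= 0 || is.na(pi_neu) || pi_neu <= 0)
    stop(structure(class = c("ratchetwave_undefined_alpha", "error",
                             "condition"),
                   list(message = "alpha undefined: requires F > 0 and pi_neu > 0",
                        call = sys.call())))
  1 - (Un * pi_sel) / (F * pi_neu)
}

#' @rdname alpha_stat
#' @param reports an `epoch_reports` object.
#' @export
measured_alpha <- function(reports, Un = NULL) {
  r <- measured_rates(reports, Un)
  if (is.null(Un)) Un <- attr(reports, "population")$Un
  alpha_stat(Un, r$pi_sel, r$pi_neu, r$F_hat)
}

#' Extract ridgeline / extremal points from a simulated grid
#'
#' Applies the grid-extraction rules used to compare simulation with
#' theory. In scaled space: the cell with the largest gamma_b among
#' cells with v < 0 gives (gamma_b*, gamma_d*). In unscaled space:
#' Nsb* is the largest Nsb with v < 0 for some parameter combination,
#' and Nsd* is the median Nsd over cells with that Nsb and v < 0.
#'
#' @param grid data.frame with per-cell `v` plus `gamma_b`/`gamma_d`
#'   (scaled) or `Nsb`/`Nsd` (unscaled) columns.
#' @param space `"scaled"` or `"unscaled"`.
#' @return named vector of the extracted point.
#' @export
ridgeline_from_grid <- function(grid, space = c("scaled", "unscaled")) {
  space <- match.arg(space)
  neg <- grid[!is.na(grid$v) & grid$v < 0, ]
  if (!nrow(neg))
    stop("no grid cell has v < 0; ridgeline extraction is undefined")
  if (space == "scaled") {
    i <- which.max(neg$gamma_b)
    c(gamma_b_star = neg$gamma_b[i], gamma_d_star = neg$gamma_d[i])
  } else {
    nsb_star <- max(neg$Nsb)
    sel <- neg[neg$Nsb == nsb_star, ]
    c(Nsb_star = nsb_star, Nsd_star = stats::median(sel$Nsd))
  }
}

#' Simulate a grid of (Nsb, Nsd) parameter combinations
#'
#' Runs the epoch protocol for every combination of `Nsb_values` and
#' `Nsd_values` at fixed eta and NU (so U = NU/N, sb = Nsb/N,
#' sd = Nsd/N), with `n_seeds` independent replicates per cell. Seeds
#' are derived deterministically from `base_seed` so any cell can be
#' re-run in isolation.
#'
#' @param Nsb_values,Nsd_values grids of N*sb and N*sd.
#' @param eta,NU,N population-genetic parameters.
#' @param Un neutral mutation rate.
#' @param family DFE family.
#' @param n_seeds replicates per cell.
#' @param base_seed integer seed root.
#' @param max_epochs,total_gen_cap epoch-protocol budget per run.
#' @return data.frame with one row per (cell, seed): Nsb, Nsd, seed,
#'   v_hat, F_hat, Tc_hat, pi_neu, pi_sel, n_epochs, cap_exceeded.
#' @export
grid_sim <- function(Nsb_values, Nsd_values, eta, NU, N, Un = 0.01,
                     family = "two_effect", n_seeds = 3, base_seed = 1,
                     max_epochs = 25, total_gen_cap = 3000) {
  U <- NU / N
  cells <- expand.grid(Nsb = Nsb_values, Nsd = Nsd_values)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    for (s in seq_len(n_seeds)) {
      seed <- (base_seed + 7919L * (i - 1L) + s) %% .Machine$integer.max
      dfe <- dfe_spec(family, sb = cells$Nsb[i] / N, sd = cells$Nsd[i] / N,
                      eta = eta)
      pop <- wf_population(N, U, Un, dfe, seed = seed)
      rep <- run_epochs(pop, max_epochs = max_epochs,
                        first_fix_cap = total_gen_cap,
                        total_gen_cap = total_gen_cap)
      r <- suppressWarnings(measured_rates(rep, Un))
      out[[length(out) + 1L]] <- data.frame(
        Nsb = cells$Nsb[i], Nsd = cells$Nsd[i], seed = seed,
        v_hat = r$v_hat, F_hat = r$F_hat, Tc_hat = r$Tc_hat,
        pi_neu = r$pi_neu, pi_sel = r$pi_sel, n_epochs = r$n_epochs,
        cap_exceeded = attr(rep, "cap_exceeded"))
    }
  }
  do.call(rbind, out)
}
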