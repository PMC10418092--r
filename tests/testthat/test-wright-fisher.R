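neutral_dfe <- dfe_spec("two_effect", sb = 1e-3, sd = 1e-3, eta = 1)

test_that("population size and fitness bookkeeping are conserved", {
  d <- dfe_spec("exponential_pair", sb = 5e-3, sd = 5e-3, eta = 0.5)
  pop <- wf_population(80, U = 0.2, Un = 0.05, dfe = d, seed = 101)
  pop <- run_generations(pop, 150)
  expect_length(pop$X, 80)
  expect_length(pop$genomes_sel, 80)
  # per-individual X equals fixed background plus carried active effects
  fixed_bg <- sum(pop$fixed$effect[!pop$fixed$neutral])
  eff <- setNames(pop$active$effect, pop$active$id)
  for (i in c(1, 40, 80)) {
    carried <- sum(eff[as.character(pop$genomes_sel[[i]])])
    expect_equal(pop$X[i], fixed_bg + carried, tolerance = 1e-12)
  }
  # active registry matches what genotypes actually carry
  carried_ids <- sort(unique(unlist(pop$genomes_sel)))
  expect_true(all(carried_ids %in% pop$active$id))
})

test_that("degenerate cases: N = 1 fixes instantly; U = Un = 0 never fixes", {
  d <- neutral_dfe
  p1 <- wf_population(1, U = 2, Un = 0, dfe = d, seed = 5)
  p1 <- run_generations(p1, 3)
  expect_gt(nrow(p1$fixed), 0)
  expect_equal(nrow(p1$active), 0)   # everything fixes as it arises
  p0 <- wf_population(30, U = 0, Un = 0, dfe = d, seed = 5)
  rep <- run_epochs(p0, first_fix_cap = 200, total_gen_cap = 200)
  expect_true(attr(rep, "cap_exceeded"))
  expect_equal(nrow(rep), 0)
})

test_that("uniform resampling when all fitnesses are equal", {
  p <- wf_population(200, U = 0, Un = 0.5, dfe = neutral_dfe, seed = 42)
  p <- run_generations(p, 50)
  expect_true(all(p$X == 0))
  expect_true(all(p$active$effect == 0))
  expect_true(all(p$active$neutral))
})

test_that("heterozygosity: clonal zero, two-haplotype value, relabeling", {
  p <- wf_population(10, U = 0, Un = 0, dfe = neutral_dfe)
  expect_equal(measure_heterozygosity(p, "neutral"), 0)
  # two equal-frequency haplotypes differing by k = 4 selected mutations
  k <- 4; N <- 10
  p$genomes_sel <- c(rep(list(1:4), 5), rep(list(integer(0)), 5))
  p$active <- data.frame(id = 1:4, effect = rep(1e-3, 4),
                         neutral = FALSE, origin = 0L)
  pi_expected <- k * 2 * 5 * (N - 5) / (N * (N - 1))  # 20/9
  expect_equal(measure_heterozygosity(p, "selected"), pi_expected)
  expect_equal(measure_heterozygosity(p, "neutral"), 0)
  # invariant under relabeling of mutation ids
  p$genomes_sel <- c(rep(list(c(901L, 17L, 55L, 3L)), 5),
                     rep(list(integer(0)), 5))
  expect_equal(measure_heterozygosity(p, "selected"), pi_expected)
})

test_that("seeded runs are bit-reproducible", {
  d <- dfe_spec("two_effect", sb = 5e-3, sd = 8e-3, eta = 0.2)
  r1 <- run_epochs(wf_population(60, 0.1, 0.02, d, seed = 77),
                   max_epochs = 12, total_gen_cap = 5000)
  r2 <- run_epochs(wf_population(60, 0.1, 0.02, d, seed = 77),
                   max_epochs = 12, total_gen_cap = 5000)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "epoch_length"), attr(r2, "epoch_length"))
  r3 <- run_epochs(wf_population(60, 0.1, 0.02, d, seed = 78),
                   max_epochs = 12, total_gen_cap = 5000)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("epoch protocol: fixed epoch length and per-epoch records", {
  p <- wf_population(100, U = 0, Un = 0.05, dfe = neutral_dfe, seed = 12)
  rep <- run_epochs(p, max_epochs = 15)
  el <- attr(rep, "epoch_length")
  expect_gt(el, 0)
  expect_equal(rep$generation, el * seq_len(nrow(rep)))
  expect_true(all(rep$pi_neu >= 0) && all(rep$pi_sel >= 0))
  expect_true(!is.unsorted(rep$fixed_neu))
  # Tc estimator definition: pi_neu / (4 Un)
  r <- suppressWarnings(measured_rates(rep, Un = 0.05))
  expect_equal(r$Tc_hat, r$pi_neu / (4 * 0.05), tolerance = 1e-12)
})

test_that("selection shifts measured rates in the expected directions", {
  # beneficial-only: fitness climbs, selected mutations fix
  pb <- wf_population(1000, U = 1e-4, Un = 0.01,
                      dfe = dfe_spec("two_effect", sb = 0.05, sd = 0.05,
                                     eta = 1e12), seed = 3)
  rb <- run_epochs(pb, max_epochs = 15, total_gen_cap = 2e4)
  mb <- suppressWarnings(measured_rates(rb))
  expect_gt(mb$v_hat, 0)
  expect_gt(mb$F_hat, 0)
  # deleterious-only weak effects: the ratchet clicks, fitness declines
  pd <- wf_population(100, U = 0.05, Un = 0.01,
                      dfe = dfe_spec("two_effect", sb = 1e-3, sd = 1e-3,
                                     eta = 0), seed = 4)
  rd <- run_epochs(pd, max_epochs = 20, total_gen_cap = 2e4)
  md <- suppressWarnings(measured_rates(rd))
  expect_lt(md$v_hat, 0)
  # neutral: v ~ 0 and no selected fixations
  pn <- wf_population(100, U = 0, Un = 0.05, dfe = neutral_dfe, seed = 8)
  rn <- run_epochs(pn, max_epochs = 20)
  mn <- suppressWarnings(measured_rates(rn))
  expect_equal(mn$F_hat, 0)
  expect_lt(abs(mn$v_hat), 1e-10)
  expect_warning(measured_rates(run_epochs(
    wf_population(100, U = 0, Un = 0.05, dfe = neutral_dfe, seed = 9),
    max_epochs = 5)), "fewer than 10")
})

test_that("alpha statistic: limits, neutral selected class, error cases", {
  expect_equal(alpha_stat(0.01, pi_sel = 0, pi_neu = 2, F = 0.01), 1)
  # fully neutral selected class: F = U and pi_sel/pi_neu = U/Un
  U <- 0.04; Un <- 0.01; pin <- 2
  expect_equal(alpha_stat(Un, pi_sel = pin * U / Un, pi_neu = pin, F = U),
               0, tolerance = 1e-12)
  expect_error(alpha_stat(0.01, 1, 2, F = 0),
               class = "ratchetwave_undefined_alpha")
  expect_error(alpha_stat(0.01, 1, pi_neu = 0, F = 0.01),
               class = "ratchetwave_undefined_alpha")
})

test_that("grid extraction rules reproduce the printed definitions", {
  # unscaled: v < 0 iff Nsd in {10, 20} at Nsb = 5, nowhere for Nsb > 5
  grid <- expand.grid(Nsb = c(2, 5, 8), Nsd = c(5, 10, 20, 40))
  grid$v <- 1
  grid$v[grid$Nsb == 5 & grid$Nsd %in% c(10, 20)] <- -1
  grid$v[grid$Nsb == 2] <- -1   # lower Nsb also declining
  ex <- ridgeline_from_grid(grid, "unscaled")
  expect_equal(unname(ex["Nsb_star"]), 5)
  expect_equal(unname(ex["Nsd_star"]), 15)   # median of {10, 20}
  # all v > 0: extraction undefined
  grid2 <- grid; grid2$v <- abs(grid2$v)
  expect_error(ridgeline_from_grid(grid2, "unscaled"), "no grid cell")
  # scaled rule: single cell with max gamma_b among v < 0 cells
  sg <- data.frame(gamma_b = c(0.2, 0.5, 0.9), gamma_d = c(1, 2, 3),
                   v = c(-1, -1, 1))
  expect_equal(unname(ridgeline_from_grid(sg, "scaled")),
               c(0.5, 2))
})

test_that("grid_sim emits one labelled row per cell and seed", {
  g <- grid_sim(Nsb_values = c(2, 20), Nsd_values = c(2, 20), eta = 0.1,
                NU = 50, N = 250, Un = 0.02, n_seeds = 2, base_seed = 5,
                max_epochs = 6, total_gen_cap = 400)
  expect_equal(nrow(g), 8)
  expect_true(all(c("v_hat", "F_hat", "Tc_hat", "cap_exceeded") %in%
                    names(g)))
  expect_equal(length(unique(g$seed)), 8)
  # deterministic re-run
  g2 <- grid_sim(Nsb_values = c(2, 20), Nsd_values = c(2, 20), eta = 0.1,
                 NU = 50, N = 250, Un = 0.02, n_seeds = 2, base_seed = 5,
                 max_epochs = 6, total_gen_cap = 400)
  expect_identical(g, g2)
})
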