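test_that("Airy function and its least negative zero", {
  z0 <- airy_zero()
  expect_lt(abs(airy_ai(z0)), 1e-12)
  expect_equal(round(z0, 2), -2.34)
  # Ai is positive on [z0, 0] and changes sign below z0
  expect_gt(airy_ai(0), 0)
  expect_gt(airy_ai(-2), 0)
  expect_lt(airy_ai(-2.5), 0)
  # decays on the positive axis
  expect_lt(airy_ai(3), airy_ai(1))
})

test_that("MSSM fixation probability: neutral value, monotonicity, symmetry", {
  N <- 1e6; Tc <- 1e4
  expect_equal(pfix_mssm(0, Tc, N), 1 / N)
  expect_equal(pfix_mssm(1 / Tc, Tc, N), exp(1) / N, tolerance = 1e-12)
  s <- seq(-5, 5, length.out = 21) / Tc
  p <- pfix_mssm(s, Tc, N)
  expect_true(all(diff(p) > 0))
  # p(s) p(-s) = 1/N^2
  expect_equal(pfix_mssm(3e-4, Tc, N) * pfix_mssm(-3e-4, Tc, N), 1 / N^2,
               tolerance = 1e-12)
})

test_that("diffusion fixation probability: continuity and asymptotics", {
  N <- 1e5; Tc <- 500
  expect_equal(pfix_diffusion(0, Tc, N), 1 / N)
  expect_equal(pfix_diffusion(1e-14, Tc, N), 1 / N, tolerance = 1e-9)
  # strongly beneficial: ~ 4 Tc s / N
  s <- 0.05
  expect_equal(pfix_diffusion(s, Tc, N), 4 * Tc * s / N, tolerance = 1e-8)
  # strongly deleterious: ~ (4 Tc |s| / N) e^{-4 Tc |s|}
  s <- -0.02
  expect_equal(pfix_diffusion(s, Tc, N),
               4 * Tc * abs(s) / N * exp(-4 * Tc * abs(s)),
               tolerance = 1e-10)
})

test_that("MSSM and diffusion pfix differ by a factor 2 at linear order", {
  N <- 1e4; Tc <- 100
  s <- 1e-7   # Tc s = 1e-5
  lin_mssm <- (pfix_mssm(s, Tc, N) * N - 1) / (Tc * s)
  lin_diff <- (pfix_diffusion(s, Tc, N) * N - 1) / (Tc * s)
  expect_equal(lin_mssm, 1, tolerance = 1e-4)
  expect_equal(lin_diff, 2, tolerance = 1e-4)
})

test_that("v and F reduce to neutral expectations as Tc -> 0", {
  d <- dfe_spec("two_effect", sb = 1e-3, sd = 4e-3, eta = 0.5)
  U <- 0.02
  mean_eff <- 0.5 / 1.5 * 1e-3 - 1 / 1.5 * 4e-3
  expect_equal(v_rate(1e5, U, d, Tc = 1e-9), U * mean_eff,
               tolerance = 1e-6 * U * abs(mean_eff))
  expect_equal(fixation_rate(1e5, U, d, Tc = 1e-9), U, tolerance = 1e-9)
})

test_that("v vanishes on the v=0 surface and F = U on the F=U surface", {
  Tc <- 1234; U <- 0.01; N <- 1e5
  gb <- 0.8; gd <- 1.6
  eta <- eta_on_surface(gb, gd, "two_effect", "v0")
  d <- dfe_spec("two_effect", sb = gb / Tc, sd = gd / Tc, eta = eta)
  expect_lt(abs(v_rate(N, U, d, Tc)) / (U * gd / Tc), 1e-12)
  eta_fu <- eta_on_surface(gb, gd, "two_effect", "fu")
  d_fu <- dfe_spec("two_effect", sb = gb / Tc, sd = gd / Tc, eta = eta_fu)
  expect_equal(fixation_rate(N, U, d_fu, Tc), U, tolerance = 1e-12)
})

test_that("deleterious-only rates: v < 0 and F -> 0 under strong purging", {
  U <- 0.05; Tc <- 2000; sd <- 1e-2   # Tc sd = 20
  d <- dfe_spec("two_effect", sb = sd, sd = sd, eta = 0)
  expect_equal(v_rate(1e4, U, d, Tc), -U * sd * exp(-Tc * sd),
               tolerance = 1e-12)
  expect_lt(fixation_rate(1e4, U, d, Tc), U * 1e-8)
})

test_that("v_rate and fixation_rate are linear in U at fixed Tc", {
  d <- dfe_spec("exponential_pair", sb = 1e-4, sd = 5e-4, eta = 0.2)
  Tc <- 800
  expect_equal(v_rate(1e5, 0.06, d, Tc), 3 * v_rate(1e5, 0.02, d, Tc),
               tolerance = 1e-12)
  expect_equal(fixation_rate(1e5, 0.06, d, Tc),
               3 * fixation_rate(1e5, 0.02, d, Tc), tolerance = 1e-12)
})

test_that("sign of v matches the sign of the scaled v0 residual", {
  set.seed(5)
  for (i in 1:10) {
    gb <- runif(1, 0.1, 1.5); gd <- runif(1, 0.1, 3)
    eta <- runif(1, 0.01, 1); Tc <- 10^runif(1, 2, 4)
    d <- dfe_spec("two_effect", sb = gb / Tc, sd = gd / Tc, eta = eta)
    r <- surface_residual(two_eff(gb, gd, eta), "v0")
    expect_equal(sign(v_rate(1e5, 0.01, d, Tc)), sign(r))
  }
})

test_that("solve_Tc is self-consistent against an independent bisection", {
  d <- dfe_spec("two_effect", sb = 5e-3, sd = 1e-2, eta = 0.1)
  sol <- suppressWarnings(solve_Tc(1e3, 0.1, d))
  expect_lt(abs(sol$residual), 1e-8)
  # independent oracle: plain bisection of the printed relation around
  # the root, using only the solution's bracket
  g <- function(Tc) ratchetwave:::.mssm_pieces(Tc, 1e3, 0.1, d)$g
  lo <- sol$Tc * 0.9; hi <- sol$Tc * 1.1
  expect_true(sign(g(lo)) != sign(g(hi)))
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
  }
  expect_equal(sol$Tc, (lo + hi) / 2, tolerance = 1e-9)
  # plugging Tc back into the relation
  expect_lt(abs(g(sol$Tc)), 1e-8)
  # solution components are coherent
  expect_equal(sol$v, v_rate(1e3, 0.1, d, sol$Tc), tolerance = 1e-12)
  expect_equal(sol$F, fixation_rate(1e3, 0.1, d, sol$Tc), tolerance = 1e-12)
  expect_equal(sol$z0, airy_zero())
  expect_true(sol$Tc > 0)
})

test_that("solve_Tc reports validity diagnostics and warns when marginal", {
  d <- dfe_spec("two_effect", sb = 5e-3, sd = 1e-2, eta = 0.1)
  sol <- suppressWarnings(solve_Tc(1e3, 0.1, d))
  expect_named(sol$validity,
               c("Tc_dxf", "Tc_Ub", "s_tilde_b", "s_tilde_d",
                 "s_tilde_b_over_dxf", "s_tilde_d_over_dxf"))
  expect_equal(sol$validity$Tc_Ub, sol$Tc * 0.1 * 0.1 / 1.1,
               tolerance = 1e-10)
  # weak-beneficial configuration triggers the Tc*Ub warning
  d2 <- dfe_spec("two_effect", sb = 5e-3, sd = 1e-2, eta = 1e-4)
  # both the Tc*Ub and Tc*b margins are flagged here
  ws <- capture_warnings(solve_Tc(1e3, 0.1, d2))
  expect_true(any(grepl("Tc \\* Ub", ws)))
})

test_that("more background selection shortens the coalescence timescale", {
  # increasing Ud at fixed N and fixed beneficial supply Ub strictly
  # decreases Tc
  N <- 1e3; Ub <- 0.01
  etas <- c(0.5, 0.3, 0.15, 0.08)
  Tcs <- vapply(etas, function(eta) {
    U <- Ub * (1 + eta) / eta
    d <- dfe_spec("two_effect", sb = 5e-3, sd = 1e-2, eta = eta)
    suppressWarnings(solve_Tc(N, U, d))$Tc
  }, 0)
  expect_true(all(diff(Tcs) < 0))
})

test_that("Ne-based heuristic: exact limits", {
  d <- dfe_spec("two_effect", sb = 1e-3, sd = 0.02, eta = 0)
  # Ud = 0: no background selection, Tc = N
  expect_equal(tc_ne_heuristic(5e4, 0, d), 5e4)
  # strong selection: N e^{-Ud/sd}
  Tc <- tc_ne_heuristic(1e5, 0.05, d)
  expect_gt(Tc * 0.02, 10)
  expect_equal(Tc, 1e5 * exp(-0.05 / 0.02), tolerance = 1e-6)
  # weak effects: fixed point of Tc = N e^{-Ud Tc sd ... } with
  # (1 - e^{-Tc s})/s -> Tc; oracle by uniroot
  dw <- dfe_spec("two_effect", sb = 1e-6, sd = 1e-6, eta = 0)
  N <- 1e3; Ud <- 0.05
  Tc_w <- tc_ne_heuristic(N, Ud, dw)
  oracle <- uniroot(function(x) x - N * exp(-Ud * (1 - exp(-x * 1e-6)) /
                                              1e-6), c(1, N),
                    tol = 1e-10)$root
  expect_equal(Tc_w, oracle, tolerance = 1e-8)
  # residual of the fixed point is tiny
  I <- (1 - exp(-Tc * 0.02)) / 0.02
  expect_lt(abs(Tc - 1e5 * exp(-0.05 * I)) / Tc, 1e-10)
})

test_that("critical census size: self-consistency and monotonicity in eta", {
  U <- 0.1
  d <- dfe_spec("two_effect", sb = 5e-3, sd = 1e-2, eta = 0.02)
  N0 <- critical_population_size(U, d, bracket = c(1e2, 1e8))
  v_at <- function(N) suppressWarnings(solve_Tc(N, U, d))$v
  expect_lt(abs(v_at(N0)) / (U * d$sd), 1e-6)
  # v > 0 above N0, v < 0 below (on the bracket)
  expect_gt(v_at(N0 * 3), 0)
  expect_lt(v_at(N0 / 3), 0)
  # raising eta makes adaptation easier: N0 decreases
  d2 <- dfe_spec("two_effect", sb = 5e-3, sd = 1e-2, eta = 0.03)
  expect_lt(critical_population_size(U, d2, bracket = c(1e2, 1e8)), N0)
  # far above the always-adapt threshold there is no crossing
  d3 <- dfe_spec("two_effect", sb = 5e-3, sd = 1e-2, eta = 10)
  expect_error(critical_population_size(U, d3, bracket = c(1e3, 1e6)),
               "same sign")
})
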