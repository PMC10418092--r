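test_that("the two-effect v=0 relation zeroes the residual", {
  set.seed(7)
  for (i in 1:15) {
    gb <- runif(1, 0.05, 2)
    gd <- runif(1, 0.05, 4)
    eta <- gd * exp(-gd) / (gb * exp(gb))
    expect_lt(abs(surface_residual(two_eff(gb, gd, eta), "v0")), 1e-14)
  }
})

test_that("a symmetric two-effect DFE always adapts", {
  # eta = 1, gamma_b = gamma_d = gamma > 0: residual
  # (gamma/2)(e^gamma - e^-gamma) > 0
  for (g in c(0.1, 0.5, 1, 3)) {
    r <- surface_residual(two_eff(g, g, 1), "v0")
    expect_equal(r, g * (exp(g) - exp(-g)) / 2, tolerance = 1e-13)
    expect_gt(r, 0)
  }
})

test_that("closed-form eta matches the residual-bisection oracle", {
  set.seed(11)
  for (i in 1:12) {
    gb <- runif(1, 0.1, 0.9)
    gd <- runif(1, 0.1, 3)
    for (surface in c("v0", "fu", "alpha0")) {
      closed <- eta_on_surface(gb, gd, "two_effect", surface)
      oracle <- eta_bisect_oracle(gb, gd, "two_effect", surface)
      expect_equal(closed, oracle, tolerance = 1e-8)
    }
    # exponential v=0 closed form (requires gamma_b < 1)
    closed <- eta_on_surface(gb, gd, "exponential_pair", "v0")
    expect_equal(closed, (gd / gb) * ((1 - gb) / (1 + gd))^2,
                 tolerance = 1e-12)
    expect_equal(closed,
                 eta_bisect_oracle(gb, gd, "exponential_pair", "v0"),
                 tolerance = 1e-8)
  }
})

test_that("substituting the closed-form eta back gives residual < 1e-10", {
  for (p in list(c(1, 1), c(0.3, 2), c(0.8, 0.4))) {
    for (surface in c("v0", "fu", "alpha0")) {
      eta <- eta_on_surface(p[1], p[2], "two_effect", surface)
      expect_lt(abs(surface_residual(two_eff(p[1], p[2], eta), surface)),
                1e-10)
    }
  }
})

test_that("known surface values: symmetric points and neutral limit", {
  expect_equal(eta_on_surface(1, 1, "two_effect", "v0"), exp(-2),
               tolerance = 1e-12)
  # F=U at gamma_b = gamma_d = gamma: (1 - e^-g)/(e^g - 1) = e^-g
  for (g in c(0.5, 1, 2))
    expect_equal(eta_on_surface(g, g, "two_effect", "fu"), exp(-g),
                 tolerance = 1e-12)
  # neutral limit: surfaces merge at eta = gamma_d / gamma_b
  expect_equal(eta_on_surface(1e-6, 1e-6, "two_effect", "v0"), 1,
               tolerance = 1e-5)
  for (surface in c("v0", "fu", "alpha0"))
    expect_equal(eta_on_surface(2e-6, 3e-6, "two_effect", surface),
                 1.5, tolerance = 1e-4)
})

test_that("eta * gamma_b <= gamma_d on the two-effect v=0 surface", {
  # neutral-accumulation bound: eta = gamma_d/gamma_b only in the
  # gamma -> 0 limit, below it everywhere else
  set.seed(3)
  for (i in 1:25) {
    gb <- runif(1, 0.01, 3)
    gd <- runif(1, 0.01, 5)
    eta <- eta_on_surface(gb, gd, "two_effect", "v0")
    expect_lte(eta * gb, gd)
  }
  expect_equal(eta_on_surface(1e-7, 2e-7, "two_effect", "v0") * 1e-7,
               2e-7, tolerance = 1e-5)
})

test_that("ridgeline sits at gamma_d* = 1 with the Lambert-W gamma_b*", {
  for (eta in c(0.05, 0.3, 1)) {
    r <- ridgeline("two_effect", eta)
    expect_equal(unname(r["gamma_d_star"]), 1)
    expect_equal(unname(r["gamma_b_star"]), lambert_bisect(1 / (exp(1) * eta)),
                 tolerance = 1e-10)
    # the ridge point really lies on the v=0 surface at this eta
    expect_equal(eta_on_surface(r["gamma_b_star"], 1, "two_effect", "v0"),
                 eta, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # numeric maximisation at fixed gamma_b recovers gamma_d* = 1
  expect_equal(ridgeline_gamma_d("two_effect", 0.5)$gamma_d_star, 1,
               tolerance = 1e-8)
})

test_that("exponential ridgeline: gamma_b* = 1 + 2 eta - 2 sqrt(eta^2+eta)", {
  for (eta in c(0.1, 0.25, 1)) {
    r <- ridgeline("exponential_pair", eta)
    gb <- unname(r["gamma_b_star"])
    expect_equal(gb, 1 + 2 * eta - 2 * sqrt(eta^2 + eta), tolerance = 1e-12)
    # it satisfies eta = (1/gb)((1-gb)/2)^2, the on-ridge v=0 relation
    expect_equal((1 / gb) * ((1 - gb) / 2)^2, eta, tolerance = 1e-10)
    # and maximises eta over gamma_d by quadrature
    expect_equal(eta_on_surface(gb, 1, "exponential_pair", "v0",
                                method = "quadrature"), eta,
                 tolerance = 1e-7)
  }
  expect_equal(
    ridgeline_gamma_d("exponential_pair", 0.3,
                      method = "quadrature")$gamma_d_star,
    1, tolerance = 1e-6)
})

test_that("always-adapt threshold is the Lambert W of 1/(e eta)", {
  expect_equal(adaptation_threshold(1 / exp(1)), lambert_bisect(1),
               tolerance = 1e-10)
  expect_equal(adaptation_threshold(1e6), 0, tolerance = 1e-5)
  # large-argument asymptotics W(x) ~ log x - log log x
  x <- 1e8
  eta <- 1 / (exp(1) * x)
  expect_equal(adaptation_threshold(eta) / (log(x) - log(log(x))), 1,
               tolerance = 0.05)
  # above the threshold the population adapts for EVERY gamma_d
  eta <- 0.2
  gb_star <- adaptation_threshold(eta)
  gds <- exp(seq(log(0.01), log(30), length.out = 40))
  resid <- vapply(gds, function(gd)
    surface_residual(two_eff(gb_star * 1.02, gd, eta), "v0"), 0)
  expect_true(all(resid > 0))
  # just below it, some gamma_d gives decline
  resid2 <- vapply(gds, function(gd)
    surface_residual(two_eff(gb_star * 0.98, gd, eta), "v0"), 0)
  expect_true(any(resid2 < 0))
})

test_that("surface ordering eta_v0 < eta_alpha0 < eta_fu holds on sweeps", {
  o <- surface_ordering(1, 1, "two_effect")
  expect_equal(unname(o["eta_v0"]), exp(-2), tolerance = 1e-12)
  expect_equal(unname(o["eta_fu"]), exp(-1), tolerance = 1e-12)
  expect_true(o["eta_v0"] < o["eta_alpha0"] &&
                o["eta_alpha0"] < o["eta_fu"])
  set.seed(19)
  for (i in 1:100) {
    gb <- runif(1, 0.05, 0.95)
    gd <- runif(1, 0.05, 5)
    o <- surface_ordering(gb, gd, "two_effect")
    expect_true(o["eta_v0"] < o["eta_alpha0"] &&
                  o["eta_alpha0"] < o["eta_fu"])
  }
  # surfaces merge to gamma_d/gamma_b at neutrality
  o <- surface_ordering(1e-6, 2e-6, "two_effect")
  expect_equal(unname(o), rep(2, 3), tolerance = 1e-4)
})

test_that("F=U surface: monotonicity and the large-gamma_d limit", {
  eta <- 0.2
  gds <- c(0.5, 1, 2, 5, 20, 100)
  etas <- vapply(gds, function(gd)
    eta_on_surface(0.8, gd, "two_effect", "fu"), 0)
  expect_true(all(diff(etas) > 0))   # increases with gamma_d
  gbs <- c(0.2, 0.5, 1, 2)
  etas_b <- vapply(gbs, function(gb)
    eta_on_surface(gb, 1, "two_effect", "fu"), 0)
  expect_true(all(diff(etas_b) < 0))  # decreases with gamma_b
  # on-surface gamma_b -> log(1 + 1/eta) as gamma_d -> infinity
  f <- function(gb) eta_on_surface(gb, 1e4, "two_effect", "fu") - eta
  gb_lim <- uniroot(f, c(0.01, 10), tol = 1e-12)$root
  expect_equal(gb_lim, log(1 + 1 / eta), tolerance = 1e-6)
})

test_that("exponential v=0 tail: eta * gamma_d -> (1-gamma_b)^2/gamma_b", {
  gb <- 0.4
  for (gd in c(100, 1000)) {
    eta <- eta_on_surface(gb, gd, "exponential_pair", "v0")
    expect_equal(eta * gd, (1 - gb)^2 / gb, tolerance = 30 / gd)
  }
})

test_that("divergence boundary localises to mean scaled effect 1", {
  expect_equal(divergence_threshold(tol = 1e-8), 1, tolerance = 1e-7)
  expect_error(divergence_threshold(interval = c(1.1, 1.5)))
})
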