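# shared fixtures, built in code

two_eff <- function(gb = 1, gd = 1, eta = 1)
  scaled_dfe("two_effect", gamma_b = gb, gamma_d = gd, eta = eta)

expo <- function(gb = 0.3, gd = 1, eta = 0.1)
  scaled_dfe("exponential_pair", gamma_b = gb, gamma_d = gd, eta = eta)

# independent oracle: eta placing a two-component point on a surface,
# found by sign-bisection of the residual on log eta (no closed forms)
eta_bisect_oracle <- function(gamma_b, gamma_d, family, surface,
                              tol = 1e-12) {
  resid <- function(eta)
    surface_residual(scaled_dfe(family, gamma_b = gamma_b,
                                gamma_d = gamma_d, eta = eta), surface)
  lo <- 1e-12; hi <- 1e3
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (resid(mid) < 0) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

# independent oracle for Lambert W: bisection of w e^w = x
lambert_bisect <- function(x, tol = 1e-13) {
  lo <- 0; hi <- max(1, log(x + 1) + 1)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mid * exp(mid) < x) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
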