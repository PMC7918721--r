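test_that("partial averaging recovers rigid and isotropic limits", {
  tens <- magnetic_tensors(A = c(0.63, 0.58, 3.36),
                           g = c(2.0088, 2.0061, 2.0027))
  rigid <- partial_average(tens, S = 1)
  expect_equal(rigid$A_par, 3.36, tolerance = 1e-12)
  expect_equal(rigid$A_perp, 0.605, tolerance = 1e-12)
  expect_equal(rigid$g_par, 2.0027, tolerance = 1e-12)

  iso <- partial_average(tens, S = 0)
  a_iso <- mean(c(0.63, 0.58, 3.36))
  expect_equal(iso$A_par, a_iso, tolerance = 1e-12)
  expect_equal(iso$A_perp, a_iso, tolerance = 1e-12)

  # polarity factor scales the isotropic average multiplicatively
  pol <- partial_average(tens, S = 0, pA = 1.05)
  expect_equal(pol$A_par, 1.05 * a_iso, tolerance = 1e-12)
  expect_equal(pol$A_par, 1.5995, tolerance = 1e-4)
})

test_that("trace is conserved and averaging is monotone in S", {
  tens <- magnetic_tensors()
  a_iso <- mean(tens$A)
  g_iso <- mean(tens$g)
  S_grid <- seq(0, 1, by = 0.05)
  prev <- NULL
  for (S in S_grid) {
    e <- partial_average(tens, S, pA = 1.02, pg = 1.0005)
    expect_equal((e$A_par + 2 * e$A_perp) / 3, 1.02 * a_iso,
                 tolerance = 1e-12)
    expect_equal((e$g_par + 2 * e$g_perp) / 3, 1.0005 * g_iso,
                 tolerance = 1e-12)
    if (!is.null(prev)) {
      expect_gte(e$A_par, prev$A_par)
      expect_lte(e$A_perp, prev$A_perp)
    }
    prev <- e
  }
  expect_error(partial_average(tens, S = 1.2), "order parameter")
})

test_that("cone angle inverts the wobble-cone relation", {
  expect_equal(cone_angle_from_order(1), 0, tolerance = 1e-8)
  expect_equal(cone_angle_from_order(0), 90, tolerance = 1e-8)
  expect_equal(cone_angle_from_order(0.37), 60.33, tolerance = 0.01)
  # round trip: S = cos(t)(1 + cos(t))/2
  S <- runif(20)
  th <- cone_angle_from_order(S, degrees = FALSE)
  expect_equal(cos(th) * (1 + cos(th)) / 2, S, tolerance = 1e-10)
  # monotone decreasing
  expect_true(all(diff(cone_angle_from_order(seq(0, 1, 0.1))) < 0))
})

test_that("resonance condition places the hyperfine triplet correctly", {
  tens <- magnetic_tensors()
  eff <- list(A_par = 1, A_perp = 1, g_par = 2.0060, g_perp = 2.0060)
  expect_equal(resonance_field(eff, 0, 0, 9.59), 341.6, tolerance = 0.1)

  eff2 <- partial_average(tens, S = 0.5)
  for (th in c(0, pi / 6, pi / 3, pi / 2)) {
    c2 <- cos(th)^2
    A_eff <- sqrt(eff2$A_par^2 * c2 + eff2$A_perp^2 * (1 - c2))
    lo <- resonance_field(eff2, th, +1)
    hi <- resonance_field(eff2, th, -1)
    expect_equal(hi - lo, 2 * A_eff, tolerance = 1e-10)
  }
  # rigid limit at theta = 0: hyperfine offset is A_zz
  rig <- partial_average(tens, S = 1)
  off <- resonance_field(rig, 0, 0) - resonance_field(rig, 0, +1)
  expect_equal(off, 3.36, tolerance = 1e-10)
})

test_that("motional linewidth vanishes at S = 1 and is linear in tau_c", {
  tens <- magnetic_tensors()
  for (tc in c(0.3, 1, 4)) {
    d <- domain_params(S = 1, tau_c = tc, W = 0.13)
    expect_equal(line_width(d, tens, pi / 5, -1), 0.13, tolerance = 1e-12)
  }
  d1 <- domain_params(S = 0.37, tau_c = 1, W = 0.1)
  d2 <- domain_params(S = 0.37, tau_c = 2, W = 0.1)
  for (mI in c(-1, 0, 1)) {
    w1 <- line_width(d1, tens, pi / 4, mI)
    w2 <- line_width(d2, tens, pi / 4, mI)
    expect_gt(w1, 0.1)  # motion does broaden
    expect_equal(w2 - 0.1, 2 * (w1 - 0.1), tolerance = 1e-10)
  }
})

test_that("component normalization contracts hold on the output grid", {
  doms <- list(domain_params(S = 0.8, tau_c = 3, W = 0.2),
               domain_params(S = 0.37, tau_c = 1.2, W = 0.1),
               domain_params(S = 0.05, tau_c = 0.3, W = 0.05))
  for (d in doms) {
    sp <- simulate_component(d, settings = fast_settings())
    ab <- attr(sp, "absorption")
    # reconstructed absorption from the returned derivative
    ab_rec <- drop(pracma::cumtrapz(sp$field, sp$intensity))
    expect_equal(pracma::trapz(sp$field, ab_rec), 1, tolerance = 1e-6)
    expect_lt(abs(pracma::trapz(sp$field, sp$intensity)), 1e-6)
    expect_equal(ab, ab_rec, tolerance = 1e-9)
  }
  expect_error(simulate_component(doms[[1]], field = c(1, 2, 3)),
               "degenerate field grid")
})

test_that("analytic derivative matches numerical differentiation of the absorption", {
  set.seed(5)
  for (i in 1:6) {
    d <- domain_params(S = runif(1), tau_c = runif(1, 0.2, 4),
                       pA = runif(1, 0.9, 1.1), W = runif(1, 0.05, 0.3))
    sp <- simulate_component(d, settings = fast_settings())
    ab <- attr(sp, "absorption")
    num <- diff(ab) / diff(sp$field)
    mid <- (sp$intensity[-1] + sp$intensity[-length(sp$intensity)]) / 2
    expect_lt(max(abs(num - mid)), 0.005 * max(abs(sp$intensity)))
  }
})

test_that("Gauss-Legendre powder average matches Monte-Carlo orientation sampling", {
  set.seed(99)
  for (rep in 1:20) {
    d <- domain_params(S = runif(1, 0.05, 0.9), tau_c = runif(1, 0.2, 3),
                       pA = runif(1, 0.9, 1.1), W = runif(1, 0.05, 0.3))
    expect_lt(mc_quadrature_gap(d), 0.01)
  }
})

test_that("isotropic limit gives an equally spaced near-equal triplet", {
  tens <- magnetic_tensors()
  d <- domain_params(S = 0, tau_c = 0.001, W = 0.08)
  sp <- simulate_component(d, tens)
  a_iso <- mean(tens$A)
  ab <- attr(sp, "absorption")
  C1 <- 6.62607015e-34 * 9.59e9 / 9.2740100783e-24 * 1e3
  centre <- C1 / mean(tens$g)
  # three absorption peaks at centre -/+ a_iso with near-equal heights
  found <- sort(vapply(c(-1, 0, 1), function(m) {
    w <- abs(sp$field - (centre - m * a_iso)) < a_iso / 2
    sp$field[w][which.max(ab[w])]
  }, 0))
  expect_equal(diff(found), rep(a_iso, 2), tolerance = 0.02)
  hts <- vapply(c(-1, 0, 1), function(m) {
    w <- abs(sp$field - (centre - m * a_iso)) < a_iso / 2
    max(ab[w])
  }, 0)
  expect_lt(diff(range(hts)) / max(hts), 0.02)
})

test_that("tau_c -> 0 recovers the W-only spectrum", {
  # reference: same line positions, widths fixed at exactly W, built from
  # the generic Lorentzian accumulator over the same powder nodes
  tens <- magnetic_tensors()
  settings <- fast_settings()
  W <- 0.15
  sp <- simulate_component(domain_params(S = 0.4, tau_c = 1e-9, W = W),
                           tens, settings = settings)
  gl <- pracma::gaussLegendre(64, 0, 1)
  eff <- partial_average(tens, 0.4)
  B0 <- c(vapply(c(-1, 0, 1), function(m)
    resonance_field(eff, acos(gl$x), m,
                    settings$microwave_frequency), numeric(64)))
  wts <- rep(gl$w / 3, 3)
  raw <- ghostepr:::cpp_lorentzian_deriv_sum(sp$field, B0,
                                             rep(W, length(B0)), wts)
  ref <- ghostepr:::.normalize_deriv(sp$field, raw)$deriv
  expect_lt(max(abs(sp$intensity - ref)), 1e-4 * max(abs(ref)))
})

test_that("superposition is linear in the proportions", {
  d1 <- domain_params(S = 0.5, tau_c = 2, d = 1)
  single <- simulate_spectrum(list(d1), settings = fast_settings())
  comp <- simulate_component(d1, settings = fast_settings())
  expect_equal(single$intensity, comp$intensity, tolerance = 1e-12)

  da <- domain_params(S = 0.5, tau_c = 2, d = 0.5)
  twin <- simulate_spectrum(list(da, da), settings = fast_settings())
  expect_equal(twin$intensity, comp$intensity, tolerance = 1e-12)

  bad <- list(domain_params(S = 0.5, tau_c = 2, d = 0.6),
              domain_params(S = 0.2, tau_c = 1, d = 0.6))
  expect_error(simulate_spectrum(bad), "sum to 1")
})
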