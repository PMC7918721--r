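# Shared fixture builders: everything is generated in code at test time.

# minimal settings for fast simulations in tests
fast_settings <- function(n_points = 512L)
  spectrometer_settings(n_points = n_points)

# hand-built solution cloud: `centers` is a list of K-row matrices (one per
# run archetype) with columns S, tau_c, pA, W; runs scatter around them
synthetic_cloud <- function(centers, n_runs = 40, sd = 0.004, seed = 1,
                            chi2 = NULL, d = NULL, bounds = fit_bounds()) {
  set.seed(seed)
  K <- nrow(centers)
  if (is.null(d)) d <- rep(1 / K, K)
  if (is.null(chi2)) chi2 <- runif(n_runs, 100, 103)
  solutions <- lapply(seq_len(n_runs), function(i) {
    domains <- lapply(seq_len(K), function(k) {
      domain_params(
        S = min(1, max(0, centers[k, "S"] + rnorm(1, 0, sd))),
        tau_c = max(0.06, centers[k, "tau_c"] + rnorm(1, 0, sd * 5)),
        pA = centers[k, "pA"] + rnorm(1, 0, sd / 4),
        pg = 1,
        W = max(0, centers[k, "W"] + rnorm(1, 0, sd / 2)),
        d = d[k])
    })
    structure(list(domains = domains, chi2 = chi2[i], seed = i,
                   n_evals = 0L, K = K),
              class = "fit_solution")
  })
  structure(list(solutions = solutions, spectrum_id = "synthetic",
                 bounds = bounds, K = K, n_runs = as.integer(n_runs),
                 base_seed = 1L, n_points = 1024L),
            class = "solution_cloud")
}

three_cluster_centers <- function() {
  m <- rbind(c(0.60, 2.2, 1.00, 0.12),
             c(0.37, 1.2, 1.00, 0.10),
             c(0.10, 0.5, 1.00, 0.08))
  colnames(m) <- c("S", "tau_c", "pA", "W")
  m
}

# minimal ghost_groups object for statistics tests (bypasses fitting)
fake_groups <- function(S, tau_c = rep(1, length(S)),
                        pA = rep(1, length(S)),
                        d = rep(100 / length(S), length(S))) {
  groups <- lapply(seq_along(S), function(i)
    structure(list(label = i, n_members = 10L, members = integer(),
                   mean = c(S = S[i], tau_c = tau_c[i], pA = pA[i],
                            W = 0.1),
                   se = c(S = 0.01, tau_c = 0.05, pA = 0.002, W = 0.005),
                   proportion = d[i], hull = NULL),
              class = "ghost_group"))
  structure(groups, class = "ghost_groups")
}

# Monte-Carlo powder-average oracle: random director orientations (uniform
# in cos(theta)) instead of Gauss-Legendre nodes; line positions and widths
# from the same physics, the orientation average by independent sampling.
# Returns the max abs deviation from the quadrature spectrum as a fraction
# of its peak.
mc_quadrature_gap <- function(d, tens = magnetic_tensors(),
                              settings = fast_settings(), n_mc = 1e5) {
  sp <- simulate_component(d, tens, settings)
  field <- sp$field
  u <- runif(n_mc)
  eff <- partial_average(tens, d$S, d$pA, d$pg)
  A_eff <- sqrt(eff$A_par^2 * u^2 + eff$A_perp^2 * (1 - u^2))
  g_eff <- sqrt(eff$g_par^2 * u^2 + eff$g_perp^2 * (1 - u^2))
  C1 <- 6.62607015e-34 * settings$microwave_frequency * 1e9 /
    9.2740100783e-24 * 1e3
  rig <- partial_average(tens, 1, d$pA, d$pg)
  theta0 <- cone_angle_from_order(d$S, degrees = FALSE)
  cn <- ghostepr:::.cone_nodes(theta0, 8)
  ug <- seq(0, 1, length.out = 257)
  raw <- numeric(length(field))
  for (mI in c(-1, 0, 1)) {
    vg <- vapply(ug, function(ct)
      ghostepr:::cpp_cone_variance(ct, as.integer(mI), rig$A_par,
                                   rig$A_perp, rig$g_par, rig$g_perp,
                                   C1, cn$x, cn$w, 16L), 0)
    G <- pmax(1e-3, d$W + 0.1760859630 * d$tau_c *
                stats::approx(ug, vg, xout = u)$y)
    B0 <- C1 / g_eff - mI * A_eff
    raw <- raw + ghostepr:::cpp_lorentzian_deriv_sum(
      field, B0, G, rep(1 / (3 * n_mc), n_mc))
  }
  mc <- ghostepr:::.normalize_deriv(field, raw)$deriv
  max(abs(mc - sp$intensity)) / max(abs(sp$intensity))
}

# brute-force neighbor count in normalized 4-D coordinates
brute_neighbor_counts <- function(X, radius) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    di <- sqrt(colSums((t(X) - X[i, ])^2))
    sum(di <= radius) - 1L
  }, 0)
}

# brute-force connected components under the slice-linkage rule: i~j iff
# some slice [s, s+width] (s over the same start set the implementation
# uses) contains both normalized S values and the (tau_c, W, pA) distance
# is <= radius
brute_slice_components <- function(nS, Y, slice_width, slice_step, radius) {
  n <- length(nS)
  starts <- seq(0, 1, by = slice_step)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      lo <- min(nS[i], nS[j]); hi <- max(nS[i], nS[j])
      share <- any(starts <= lo & hi <= starts + slice_width)
      if (share && sqrt(sum((Y[i, ] - Y[j, ])^2)) <= radius)
        adj[i, j] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
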