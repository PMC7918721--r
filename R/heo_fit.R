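## Hybrid evolutionary optimization (HEO): real-coded genetic algorithm
## followed by Nelder-Mead refinement, fitting a K-component lineshape model
## to a measured spectrum.  Domain proportions d are profiled out of the
## search by non-negative least squares at every objective evaluation (the
## spectrum is linear in d), so the global search runs over the 5K nonlinear
## parameters (S, tau_c, pA, pg, W per component) only.

#' Noise standard deviation estimated from the sweep tails
#'
#' Standard deviation of the intensity over the outer fraction of field
#' points (split between both sweep ends), where a first-derivative spectrum
#' of lines well inside the window is essentially baseline.
#'
#' @param spectrum an [epr_spectrum()].
#' @param tail_fraction total fraction of points used (default 0.05).
#' @return Estimated noise sd in intensity units.
#' @export
estimate_noise_sd <- function(spectrum, tail_fraction = 0.05) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  n <- length(spectrum$intensity)
  k <- max(8L, floor(tail_fraction * n / 2))
  y <- c(spectrum$intensity[seq_len(k)],
         spectrum$intensity[seq.int(n - k + 1L, n)])
  stats::sd(y)
}

#' Chi-square goodness of fit between two spectra
#'
#' `sum((y_sim - y_meas)^2) / noise_sd^2` on a common field grid.  Both
#' spectra and the noise sd are implicitly on the same amplitude scale, so
#' the statistic is invariant to a common rescaling of all three.
#'
#' @param simulated,measured [epr_spectrum()] objects on identical grids.
#' @param noise_sd noise standard deviation in intensity units; if `NULL`,
#'   estimated from the sweep tails of `measured` via [estimate_noise_sd()].
#' @return Non-negative goodness-of-fit value.
#' @export
chi_square <- function(simulated, measured, noise_sd = NULL) {
  stopifnot(inherits(simulated, "epr_spectrum"),
            inherits(measured, "epr_spectrum"))
  if (length(simulated$field) != length(measured$field) ||
      max(abs(simulated$field - measured$field)) > 1e-9)
    stop("simulated and measured spectra are on different field grids")
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(measured)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive")
  sum((simulated$intensity - measured$intensity)^2) / noise_sd^2
}

#' HEO optimizer configuration
#'
#' @param population GA population size.
#' @param generations number of GA generations.
#' @param tournament_size selection tournament size (smaller = weaker
#'   selection pressure, more diversity).
#' @param crossover_prob probability of BLX-alpha blend crossover.
#' @param crossover_alpha blend extension factor.
#' @param mutation_prob per-gene Gaussian mutation probability.
#' @param mutation_sd_frac mutation sd as a fraction of each bound width.
#' @param nm_maxit maximum Nelder-Mead iterations per refinement pass; the
#'   simplex runs in bound-normalized coordinates.
#' @param nm_restarts maximum simplex restarts (a fresh simplex at the last
#'   optimum, stopped early once an extra pass gains < `nm_tol`).
#' @param nm_tol chi-square improvement below which restarting stops.
#' @param nm_starts how many good, mutually distant GA individuals receive
#'   a simplex refinement (the best refined result is returned).
#' @param immigrant_frac fraction of each generation replaced by fresh
#'   uniform-random individuals (keeps the population exploring after the
#'   bulk converges).
#' @return A list of class `heo_config`.
#' @export
heo_config <- function(population = 96L, generations = 40L,
                       tournament_size = 2L, crossover_prob = 0.9,
                       crossover_alpha = 0.5, mutation_prob = 0.25,
                       mutation_sd_frac = 0.05, nm_maxit = 1000L,
                       nm_restarts = 3L, nm_tol = 1, nm_starts = 3L,
                       immigrant_frac = 0.15) {
  stopifnot(population >= 4, generations >= 1, tournament_size >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            mutation_sd_frac > 0, nm_maxit >= 0, nm_restarts >= 1,
            nm_tol >= 0, nm_starts >= 1, immigrant_frac >= 0,
            immigrant_frac < 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob,
                 crossover_alpha = crossover_alpha,
                 mutation_prob = mutation_prob,
                 mutation_sd_frac = mutation_sd_frac,
                 nm_maxit = as.integer(nm_maxit),
                 nm_restarts = as.integer(nm_restarts),
                 nm_tol = nm_tol,
                 nm_starts = as.integer(nm_starts),
                 immigrant_frac = immigrant_frac),
            class = "heo_config")
}

# nonlinear genome layout: (S, tau_c, pA, pg, W) per component
.gene_names <- c("S", "tau_c", "pA", "pg", "W")

.genome_bounds <- function(bounds, K) {
  lower <- rep(vapply(.gene_names, function(p) bounds[[p]][1], 0), K)
  upper <- rep(vapply(.gene_names, function(p) bounds[[p]][2], 0), K)
  list(lower = lower, upper = upper)
}

# Build the K unit-component design matrix for a genome and profile the
# proportions by non-negative least squares against the measured intensity.
.heo_objective_factory <- function(measured, K, tensors, noise_sd,
                                   n_theta, n_cone, kappa) {
  field <- measured$field
  y <- measured$intensity
  settings <- measured$settings
  gl <- pracma::gaussLegendre(n_theta, 0, 1)
  # reference cone nodes on [0,1]; any [cos(theta0), 1] interval is an
  # affine image, so the eigensolve runs once, not once per evaluation
  cn_ref <- pracma::gaussLegendre(n_cone[1], 0, 1)
  freq_Hz <- settings$microwave_frequency * 1e9
  n_evals <- 0L

  # large finite penalty for degenerate genomes (keeps Nelder-Mead stable)
  penalty <- .Machine$double.xmax / 2

  batch <- function(genomes) {
    if (!is.matrix(genomes)) genomes <- matrix(genomes, nrow = 1)
    n_evals <<- n_evals + nrow(genomes)
    cpp_heo_objective(genomes, as.integer(K), field, y,
                      tensors$A[1], tensors$A[2], tensors$A[3],
                      tensors$g[1], tensors$g[2], tensors$g[3],
                      freq_Hz, kappa, gl$x, gl$w, cn_ref$x, cn_ref$w,
                      as.integer(n_cone[2]), noise_sd, penalty)
  }

  list(chi2 = function(genome) batch(genome)$chi2[1],
       chi2_batch = function(genomes) batch(genomes)$chi2,
       full = function(genome) {
         r <- batch(genome)
         list(chi2 = r$chi2[1], d = r$d[1, ])
       },
       evals = function() n_evals)
}

.tournament <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.min(fit[cand])]
}

# one GA phase; `obj` evaluates a whole population matrix at once
.ga_phase <- function(obj, lower, upper, cfg) {
  ng <- length(lower)
  P <- cfg$population
  pop <- vapply(seq_len(ng),
                function(j) runif(P, lower[j], upper[j]),
                numeric(P))
  fit <- obj(pop)
  widths <- upper - lower
  for (gen in seq_len(cfg$generations)) {
    elite <- which.min(fit)
    newpop <- matrix(0, P, ng)
    for (i in seq_len(P)) {
      p1 <- .tournament(fit, cfg$tournament_size)
      if (runif(1) < cfg$crossover_prob) {
        p2 <- .tournament(fit, cfg$tournament_size)
        lo <- pmin(pop[p1, ], pop[p2, ])
        hi <- pmax(pop[p1, ], pop[p2, ])
        ext <- cfg$crossover_alpha * (hi - lo)
        child <- runif(ng, lo - ext, hi + ext)
      } else {
        child <- pop[p1, ]
      }
      mut <- runif(ng) < cfg$mutation_prob
      if (any(mut))
        child[mut] <- child[mut] +
          rnorm(sum(mut), 0, cfg$mutation_sd_frac * widths[mut])
      newpop[i, ] <- pmin(upper, pmax(lower, child))
    }
    n_imm <- floor(cfg$immigrant_frac * P)
    if (n_imm > 0) {
      imm_rows <- P - seq_len(n_imm) + 1L
      for (j in seq_len(ng))
        newpop[imm_rows, j] <- runif(n_imm, lower[j], upper[j])
    }
    newpop[1, ] <- pop[elite, ]
    newfit <- obj(newpop)
    newfit[1] <- fit[elite]
    pop <- newpop
    fit <- newfit
  }
  ord <- order(fit)
  list(pop = pop[ord, , drop = FALSE], fit = fit[ord])
}

# greedy selection of up to m good, mutually distant individuals (distance
# in bound-normalized coordinates) to seed the simplex refinements
.nm_start_set <- function(pop, widths, m, min_dist = 0.15) {
  picks <- 1L
  for (i in seq_len(nrow(pop))[-1]) {
    if (length(picks) >= m) break
    z <- sweep(pop[picks, , drop = FALSE], 2, pop[i, ]) /
      rep(widths, each = length(picks))
    if (min(sqrt(rowSums(z^2))) >= min_dist) picks <- c(picks, i)
  }
  picks
}

#' One hybrid evolutionary optimization run
#'
#' Fits a K-component model to `measured`: a seeded real-coded genetic
#' algorithm (tournament selection, blend crossover, Gaussian mutation,
#' elitism) searches the nonlinear parameters within `bounds`, then
#' Nelder-Mead refines the GA's best individual (parameters clipped to
#' bounds inside the objective).  Proportions are obtained by non-negative
#' least squares at every evaluation and sum to 1 exactly.  The refinement
#' never increases the goodness-of-fit value of the GA's best individual.
#'
#' @param measured an [epr_spectrum()].
#' @param K number of spectral components (1-5).
#' @param bounds a [fit_bounds()] object.
#' @param seed integer run seed; the run is bit-reproducible given the seed.
#' @param tensors a [magnetic_tensors()] object.
#' @param config an [heo_config()].
#' @param noise_sd noise sd for the chi-square scale; estimated from the
#'   spectrum tails if `NULL`.
#' @param n_theta,n_cone,kappa forward-model controls, see
#'   [simulate_component()].
#' @return A `fit_solution`: list with `domains` (K [domain_params()] with
#'   fitted `d`), `chi2`, `seed`, `n_evals`, `K`.
#' @export
heo_run <- function(measured, K = 3L, bounds = fit_bounds(), seed = 1L,
                    tensors = magnetic_tensors(), config = heo_config(),
                    noise_sd = NULL, n_theta = 64L, n_cone = c(8L, 16L),
                    kappa = .const$gamma_e) {
  stopifnot(inherits(measured, "epr_spectrum"), K >= 1, K <= 5,
            inherits(bounds, "fit_bounds"), inherits(config, "heo_config"))
  if (is.null(noise_sd)) {
    noise_sd <- estimate_noise_sd(measured)
    # noise-free synthetic input: keep the scale finite
    noise_sd <- max(noise_sd, 1e-6 * max(abs(measured$intensity)))
  }
  gb <- .genome_bounds(bounds, K)
  obj <- .heo_objective_factory(measured, K, tensors, noise_sd,
                                n_theta, n_cone, kappa)
  set.seed(as.integer(seed))
  ga <- .ga_phase(obj$chi2_batch, gb$lower, gb$upper, config)
  # simplex refinement in bound-normalized coordinates (the raw parameters
  # differ by 3 orders of magnitude in scale); several good but mutually
  # distant GA individuals are refined so distinct candidate basins each
  # get a local polish
  widths <- gb$upper - gb$lower
  to_unit <- function(g) (g - gb$lower) / widths
  from_unit <- function(z) gb$lower + pmin(1, pmax(0, z)) * widths
  unit_obj <- function(z) obj$chi2(from_unit(z))
  z_best <- to_unit(ga$pop[1, ])
  value_best <- ga$fit[1]
  if (config$nm_maxit > 0) {
    starts <- .nm_start_set(ga$pop, widths, config$nm_starts)
    for (s in starts) {
      z <- to_unit(ga$pop[s, ])
      value <- ga$fit[s]
      for (r in seq_len(config$nm_restarts)) {
        o <- stats::optim(z, unit_obj, method = "Nelder-Mead",
                          control = list(maxit = config$nm_maxit))
        gained <- value - o$value
        if (o$value <= value) {
          z <- o$par
          value <- o$value
        }
        if (gained < config$nm_tol) break
      }
      if (value < value_best) {
        z_best <- z
        value_best <- value
      }
    }
  }
  genome <- from_unit(z_best)
  final <- obj$full(genome)
  domains <- lapply(seq_len(K), function(k) {
    g <- genome[(k - 1) * 5 + 1:5]
    domain_params(S = g[1], tau_c = g[2], pA = g[3], pg = g[4], W = g[5],
                  d = final$d[k])
  })
  # guard the exact-sum invariant against floating renormalization
  ds <- vapply(domains, `[[`, 0, "d")
  domains[[K]]$d <- domains[[K]]$d + (1 - sum(ds))
  structure(list(domains = domains, chi2 = final$chi2,
                 chi2_ga = ga$fit[1], seed = as.integer(seed),
                 n_evals = obj$evals(), K = as.integer(K)),
            class = "fit_solution")
}

#' @export
print.fit_solution <- function(x, ...) {
  cat(sprintf("HEO fit: K = %d, chi2 = %.4g, seed = %d, %d evaluations\n",
              x$K, x$chi2, x$seed, x$n_evals))
  for (d in x$domains) print(d)
  invisible(x)
}

# stable fingerprint of a spectrum for provenance
.spectrum_id <- function(spectrum) {
  y <- spectrum$intensity
  sprintf("spec-n%d-%s", length(y),
          paste(format(signif(c(sum(y), sum(y^2), y[1]), 12)), collapse = "_"))
}

#' Multi-run HEO fitting
#'
#' Repeats [heo_run()] over `n_runs` independent runs with seeds
#' `base_seed + 0 .. n_runs - 1` and collects every run's solution into a
#' solution cloud for GHOST condensation.
#'
#' @param measured an [epr_spectrum()].
#' @param K number of spectral components.
#' @param bounds a [fit_bounds()].
#' @param n_runs number of independent runs (the reference protocol uses
#'   200; reduced scales are legitimate for desk-size problems).
#' @param base_seed first run seed.
#' @param ... further arguments to [heo_run()].
#' @return A `solution_cloud`: list with `solutions`, `spectrum_id`,
#'   `bounds`, `K`, `n_runs`, `base_seed`.
#' @export
multi_run <- function(measured, K = 3L, bounds = fit_bounds(),
                      n_runs = 200L, base_seed = 1L, ...) {
  stopifnot(n_runs >= 1)
  solutions <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    solutions[[i]] <- tryCatch(
      heo_run(measured, K = K, bounds = bounds,
              seed = base_seed + i - 1L, ...),
      error = function(e)
        stop("HEO run ", i, " (seed ", base_seed + i - 1L, ") failed: ",
             conditionMessage(e)))
  }
  structure(list(solutions = solutions,
                 spectrum_id = .spectrum_id(measured),
                 bounds = bounds, K = as.integer(K),
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed),
                 n_points = length(measured$field)),
            class = "solution_cloud")
}

#' @export
print.solution_cloud <- function(x, ...) {
  chi2 <- vapply(x$solutions, `[[`, 0, "chi2")
  cat(sprintf("solution cloud: %d runs, K = %d, chi2 range %.4g-%.4g\n",
              x$n_runs, x$K, min(chi2), max(chi2)))
  invisible(x)
}
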