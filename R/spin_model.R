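## Forward model: first-derivative EPR lineshape of a fast-but-restricted
## nitroxide probe, powder-averaged over director orientations, as a
## weighted superposition of domain components.

#' Motional (partial) averaging of the magnetic tensors
#'
#' Averages the rhombic hyperfine and g tensors to effective axial values for
#' a probe undergoing fast restricted rotation with order parameter `S`,
#' scaled by the polarity correction factors.  `S = 1` recovers the rigid
#' principal values (axially collapsed), `S = 0` full isotropic averaging.
#' The trace is preserved: `(A_par + 2 A_perp) / 3 = pA * a_iso`.
#'
#' @param tensors a [magnetic_tensors()] object.
#' @param S order parameter in \[0, 1\].
#' @param pA,pg polarity correction factors for the A and g tensors.
#' @return List with `A_par`, `A_perp` (mT), `g_par`, `g_perp`.
#' @export
#' @examples
#' partial_average(magnetic_tensors(), S = 0.37)
partial_average <- function(tensors, S, pA = 1, pg = 1) {
  stopifnot(inherits(tensors, "magnetic_tensors"))
  if (!is.numeric(S) || anyNA(S) || any(S < 0 | S > 1))
    stop("order parameter S must lie in [0, 1]")
  if (any(pA <= 0) || any(pg <= 0))
    stop("polarity correction factors must be positive")
  A <- tensors$A; g <- tensors$g
  a_iso <- mean(A); dA <- A[3] - (A[1] + A[2]) / 2
  g_iso <- mean(g); dg <- g[3] - (g[1] + g[2]) / 2
  list(A_par  = pA * (a_iso + 2 / 3 * S * dA),
       A_perp = pA * (a_iso - S * dA / 3),
       g_par  = pg * (g_iso + 2 / 3 * S * dg),
       g_perp = pg * (g_iso - S * dg / 3))
}

#' Wobble-cone half-angle corresponding to an order parameter
#'
#' Inverts the wobble-in-cone relation `S = cos(t0) (1 + cos(t0)) / 2` for
#' the cone half-angle `t0`.  Monotone decreasing: `S = 1` gives 0 degrees
#' (no accessible motion), `S = 0` gives 90 degrees (free hemisphere).
#'
#' @param S order parameter in \[0, 1\] (vectorized).
#' @param degrees return degrees (default) or radians.
#' @return Cone half-angle(s).
#' @export
#' @examples
#' cone_angle_from_order(c(0, 0.37, 1))
cone_angle_from_order <- function(S, degrees = TRUE) {
  if (!is.numeric(S) || anyNA(S) || any(S < 0 | S > 1))
    stop("order parameter S must lie in [0, 1]")
  ct <- (-1 + sqrt(1 + 8 * S)) / 2   # positive root of c^2 + c - 2S = 0
  th <- acos(pmin(1, pmax(-1, ct)))
  if (degrees) th * 180 / pi else th
}

#' Resonance field of one hyperfine line
#'
#' Standard high-field resonance condition for an axial spin system:
#' `B = h v / (g_eff mu_B) - m_I * A_eff`, with
#' `A_eff(theta) = sqrt(A_par^2 cos^2 + A_perp^2 sin^2)` and analogously for
#' `g_eff`.  The `m_I = +/-1` lines are symmetric about the central line
#' with spacing `A_eff(theta)`.
#'
#' @param eff effective axial tensors from [partial_average()].
#' @param theta angle between the domain director and the static field, rad.
#' @param m_I nitrogen nuclear spin projection, one of -1, 0, +1.
#' @param frequency microwave frequency in GHz.
#' @return Resonance field in mT (vectorized over `theta`).
#' @export
resonance_field <- function(eff, theta, m_I, frequency = 9.59) {
  if (!m_I %in% c(-1, 0, 1)) stop("m_I must be -1, 0 or +1")
  c2 <- cos(theta)^2
  A_eff <- sqrt(eff$A_par^2 * c2 + eff$A_perp^2 * (1 - c2))
  g_eff <- sqrt(eff$g_par^2 * c2 + eff$g_perp^2 * (1 - c2))
  C1 <- .const$h * frequency * 1e9 / .const$mu_B * 1e3
  C1 / g_eff - m_I * A_eff
}

# Gauss-Legendre nodes on cos(alpha) in [cos(theta0), 1] for the wobble cone;
# degenerate cone (S -> 1) collapses to a single zero-weight node so the
# motional variance is exactly 0.
.cone_nodes <- function(theta0, n_polar = 8) {
  ct0 <- cos(theta0)
  if (1 - ct0 < 1e-12)
    return(list(x = 1, w = 0))
  gl <- pracma::gaussLegendre(n_polar, ct0, 1)
  list(x = gl$x, w = gl$w)
}

#' Orientation-dependent Lorentzian half-width of one line
#'
#' Intrinsic broadening plus a motional-narrowing term proportional to the
#' rotational correlation time and to the variance of the instantaneous
#' (rigid-limit) resonance field over the wobble cone accessible at order
#' parameter `S`:
#' `dB(theta, m_I) = W + kappa * tau_c * Var_cone[B_inst]`.
#' The variance term vanishes at `S = 1` and the width is linear in `tau_c`.
#'
#' @param domain a [domain_params()] object.
#' @param tensors a [magnetic_tensors()] object.
#' @param theta director-field angle in rad (scalar).
#' @param m_I nuclear spin projection, -1, 0 or +1.
#' @param frequency microwave frequency in GHz.
#' @param kappa motional broadening constant in 1/(ns mT); default is the
#'   electron gyromagnetic ratio expressed in those units.
#' @param n_cone integer length 2: polar and azimuthal quadrature sizes for
#'   the cone average.
#' @return Lorentzian half-width at half-maximum in mT.
#' @export
line_width <- function(domain, tensors, theta, m_I, frequency = 9.59,
                       kappa = .const$gamma_e, n_cone = c(8L, 16L)) {
  stopifnot(inherits(domain, "domain_params"),
            inherits(tensors, "magnetic_tensors"))
  if (!m_I %in% c(-1, 0, 1)) stop("m_I must be -1, 0 or +1")
  rig <- partial_average(tensors, S = 1, pA = domain$pA, pg = domain$pg)
  theta0 <- cone_angle_from_order(domain$S, degrees = FALSE)
  cn <- .cone_nodes(theta0, n_cone[1])
  C1 <- .const$h * frequency * 1e9 / .const$mu_B * 1e3
  v <- cpp_cone_variance(cos(theta), as.integer(m_I),
                         rig$A_par, rig$A_perp, rig$g_par, rig$g_perp,
                         C1, cn$x, cn$w, as.integer(n_cone[2]))
  domain$W + kappa * domain$tau_c * v
}

# Detrend + normalize a raw analytic derivative so that (i) its trapezoid
# integral over the grid is exactly 0 and (ii) the reconstructed absorption
# (cumulative trapezoid integral) has unit trapezoid integral.
.normalize_deriv <- function(field, raw) {
  nrm <- cpp_normalize_deriv(field, raw)
  if (!isTRUE(nrm$ok))
    stop("degenerate lineshape: absorption integral is not positive ",
         "(all lines outside the sweep window?)")
  nrm[c("deriv", "absorption")]
}

# First-harmonic detection of a field-modulated absorption signal
# (pseudo-modulation), scaled so the small-amplitude limit equals the
# analytic first derivative.
.pseudo_modulate <- function(field, absorption, amplitude, n_phase = 16L) {
  phi <- 2 * pi * (seq_len(n_phase) - 0.5) / n_phase
  acc <- numeric(length(field))
  for (p in phi) {
    shifted <- stats::approx(field, absorption, xout = field +
                               amplitude / 2 * cos(p), rule = 2)$y
    acc <- acc + shifted * cos(p)
  }
  (2 / amplitude) * (2 / n_phase) * acc
}

#' Simulate one domain component
#'
#' Powder-averaged first-derivative spectrum of a single membrane domain:
#' Gauss-Legendre average over director orientations (integrand weighted by
#' sin(theta), i.e. uniform in cos(theta)) of the three nitrogen hyperfine
#' lines, each a first-derivative Lorentzian centred at [resonance_field()]
#' with half-width [line_width()].  The output is normalized so the
#' reconstructed absorption has unit double integral over the sweep and the
#' derivative integrates to zero.
#'
#' @param domain a [domain_params()] object (its `d` is ignored here).
#' @param tensors a [magnetic_tensors()] object.
#' @param settings a [spectrometer_settings()] object.
#' @param n_theta number of Gauss-Legendre powder nodes (default 64).
#' @param n_cone polar/azimuthal cone quadrature sizes, see [line_width()].
#' @param kappa motional broadening constant, see [line_width()].
#' @param field optional explicit field grid in mT (overrides `settings`).
#' @param pseudo_modulation if `TRUE`, render the first harmonic of the
#'   field-modulated absorption (modulation amplitude from `settings`)
#'   instead of the analytic derivative.
#' @return An [epr_spectrum()]; the reconstructed absorption is attached as
#'   attribute `"absorption"`.
#' @export
#' @examples
#' sp <- simulate_component(domain_params(S = 0.37, tau_c = 1.2),
#'                          magnetic_tensors(), spectrometer_settings())
simulate_component <- function(domain, tensors = magnetic_tensors(),
                               settings = spectrometer_settings(),
                               n_theta = 64L, n_cone = c(8L, 16L),
                               kappa = .const$gamma_e, field = NULL,
                               pseudo_modulation = FALSE) {
  stopifnot(inherits(domain, "domain_params"),
            inherits(tensors, "magnetic_tensors"))
  if (is.null(field)) field <- field_grid(settings)
  if (length(field) < 8 || any(diff(field) <= 0))
    stop("degenerate field grid")
  gl <- pracma::gaussLegendre(n_theta, 0, 1)
  theta0 <- cone_angle_from_order(domain$S, degrees = FALSE)
  cn <- .cone_nodes(theta0, n_cone[1])
  raw <- cpp_component_deriv(field,
                             tensors$A[1], tensors$A[2], tensors$A[3],
                             tensors$g[1], tensors$g[2], tensors$g[3],
                             domain$S, domain$tau_c, domain$pA, domain$pg,
                             domain$W, settings$microwave_frequency * 1e9,
                             kappa, gl$x, gl$w, cn$x, cn$w,
                             as.integer(n_cone[2]))
  if (!all(is.finite(raw)))
    stop("non-finite lineshape for the supplied parameters")
  nrm <- .normalize_deriv(field, raw)
  intensity <- if (pseudo_modulation) {
    .pseudo_modulate(field, nrm$absorption, settings$modulation_amplitude)
  } else nrm$deriv
  out <- epr_spectrum(field, intensity, settings,
                      provenance = list(kind = "simulated_component",
                                        params = unclass(domain)))
  attr(out, "absorption") <- nrm$absorption
  out
}

#' Simulate a multi-domain spectrum
#'
#' Pointwise weighted superposition of the domain components on a common
#' field grid, with weights `d` (the domain proportions).  Linear in `d`.
#'
#' @param domains list of [domain_params()]; their `d` must sum to 1
#'   (within 1e-9).
#' @param tensors,settings,... passed to [simulate_component()].
#' @return An [epr_spectrum()].
#' @export
#' @examples
#' doms <- list(domain_params(0.5, 2.0, d = 0.6),
#'              domain_params(0.2, 0.8, d = 0.4))
#' sp <- simulate_spectrum(doms)
simulate_spectrum <- function(domains, tensors = magnetic_tensors(),
                              settings = spectrometer_settings(), ...) {
  if (inherits(domains, "domain_params")) domains <- list(domains)
  stopifnot(length(domains) >= 1,
            all(vapply(domains, inherits, TRUE, "domain_params")))
  dsum <- sum(vapply(domains, `[[`, 0, "d"))
  if (abs(dsum - 1) > 1e-9)
    stop("domain proportions must sum to 1 (got ", format(dsum), ")")
  comps <- lapply(domains, simulate_component, tensors = tensors,
                  settings = settings, ...)
  intensity <- Reduce(`+`, Map(function(cp, dm) dm$d * cp$intensity,
                               comps, domains))
  absorb <- Reduce(`+`, Map(function(cp, dm) dm$d * attr(cp, "absorption"),
                            comps, domains))
  out <- epr_spectrum(comps[[1]]$field, intensity, settings,
                      provenance = list(kind = "simulated_spectrum",
                                        n_domains = length(domains)))
  attr(out, "absorption") <- absorb
  out
}
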