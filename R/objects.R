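## Core value objects of the pipeline.  Plain lists with S3 classes and
## strict constructors, in the style of survival/ape.

#' Nitroxide magnetic tensors
#'
#' Principal values of the \eqn{^{14}}N hyperfine tensor (mT) and the g
#' tensor of the spin probe.  The defaults are standard doxyl-nitroxide
#' literature values for a 5-doxyl fatty-acid probe; they are package
#' defaults, not measured constants, and every function taking tensors
#' accepts overrides.
#'
#' @param A numeric length 3, principal hyperfine values
#'   \code{c(A_xx, A_yy, A_zz)} in mT; \code{A_zz} must exceed the other two.
#' @param g numeric length 3, principal g values \code{c(g_xx, g_yy, g_zz)},
#'   each within \[2.000, 2.012\].
#' @return An object of class \code{magnetic_tensors}.
#' @export
#' @examples
#' magnetic_tensors()
magnetic_tensors <- function(A = c(0.63, 0.58, 3.36),
                             g = c(2.0088, 2.0061, 2.0027)) {
  stopifnot(is.numeric(A), length(A) == 3, is.numeric(g), length(g) == 3)
  if (any(A <= 0))
    stop("hyperfine principal values must be positive")
  if (!(A[3] > A[1] && A[3] > A[2]))
    stop("nitroxide geometry requires A_zz > A_xx and A_zz > A_yy")
  if (any(g < 2.000 | g > 2.012))
    stop("g principal values must lie within [2.000, 2.012]")
  structure(list(A = as.numeric(A), g = as.numeric(g)),
            class = "magnetic_tensors")
}

#' One membrane domain's spectral parameters
#'
#' @param S order parameter, in \[0, 1\]; 1 = perfectly ordered, 0 =
#'   isotropic motion.
#' @param tau_c rotational correlation time in ns (> 0).
#' @param pA hyperfine polarity correction factor (multiplies the A tensor).
#' @param pg g-tensor polarity correction factor.
#' @param W residual Lorentzian broadening constant in mT (>= 0).
#' @param d proportion of spin probes in this domain, in \[0, 1\].
#' @return An object of class \code{domain_params}.
#' @export
#' @examples
#' domain_params(S = 0.37, tau_c = 1.2)
domain_params <- function(S, tau_c, pA = 1, pg = 1, W = 0.1, d = 1) {
  vals <- vapply(list(S, tau_c, pA, pg, W, d), function(v)
    as.numeric(v)[1], 0)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("all domain parameters must be finite numerics")
  if (S < 0 || S > 1) stop("order parameter S must lie in [0, 1]")
  if (tau_c <= 0) stop("tau_c must be positive")
  if (W < 0) stop("W must be non-negative")
  if (d < 0 || d > 1) stop("proportion d must lie in [0, 1]")
  structure(list(S = vals[1], tau_c = vals[2], pA = vals[3], pg = vals[4],
                 W = vals[5], d = vals[6]), class = "domain_params")
}

#' @export
print.domain_params <- function(x, ...) {
  cat(sprintf(
    "domain: S = %.3f, tau_c = %.3g ns, pA = %.4f, pg = %.5f, W = %.3f mT, d = %.3f\n",
    x$S, x$tau_c, x$pA, x$pg, x$W, x$d))
  invisible(x)
}

#' Spectrometer acquisition settings
#'
#' @param microwave_frequency microwave frequency in GHz.
#' @param center_field centre of the field sweep in mT.
#' @param sweep_width width of the field sweep in mT (> 0).
#' @param n_points number of field points (>= 128).
#' @param modulation_amplitude field modulation amplitude in mT (metadata;
#'   the default rendering is the analytic first derivative).
#' @param temperature sample temperature in degrees Celsius (metadata only).
#' @return An object of class \code{spectrometer_settings}.
#' @export
spectrometer_settings <- function(microwave_frequency = 9.59,
                                  center_field = 341.5,
                                  sweep_width = 10,
                                  n_points = 1024L,
                                  modulation_amplitude = 0.2,
                                  temperature = 20) {
  if (n_points < 128) stop("n_points must be >= 128")
  if (sweep_width <= 0) stop("sweep_width must be positive")
  if (microwave_frequency <= 0) stop("microwave_frequency must be positive")
  structure(list(microwave_frequency = microwave_frequency,
                 center_field = center_field,
                 sweep_width = sweep_width,
                 n_points = as.integer(n_points),
                 modulation_amplitude = modulation_amplitude,
                 temperature = temperature),
            class = "spectrometer_settings")
}

#' Field grid of a settings object
#'
#' Uniform ascending grid of \code{n_points} field values spanning
#' \code{center_field +/- sweep_width/2}, in mT.
#'
#' @param settings a [spectrometer_settings()] object.
#' @return Numeric vector of field positions in mT.
#' @export
field_grid <- function(settings) {
  stopifnot(inherits(settings, "spectrometer_settings"))
  seq(settings$center_field - settings$sweep_width / 2,
      settings$center_field + settings$sweep_width / 2,
      length.out = settings$n_points)
}

#' Construct an EPR spectrum
#'
#' @param field ascending, uniform field grid in mT.
#' @param intensity first-derivative amplitude (arbitrary units), same
#'   length as \code{field}.
#' @param settings a [spectrometer_settings()] object.
#' @param provenance free-form metadata list.
#' @return An object of class \code{epr_spectrum} with elements
#'   \code{field}, \code{intensity}, \code{settings}, \code{provenance}.
#' @export
epr_spectrum <- function(field, intensity, settings = spectrometer_settings(),
                         provenance = list()) {
  field <- as.numeric(field)
  intensity <- as.numeric(intensity)
  if (length(field) != length(intensity))
    stop("field and intensity must have the same length")
  if (length(field) < 2 || any(diff(field) <= 0))
    stop("field must be strictly increasing with at least 2 points")
  structure(list(field = field, intensity = intensity,
                 settings = settings, provenance = provenance),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf("EPR spectrum: %d points, %.2f-%.2f mT, peak |I| = %.3g\n",
              length(x$field), min(x$field), max(x$field),
              max(abs(x$intensity))))
  invisible(x)
}

#' @export
plot.epr_spectrum <- function(x, ...) {
  graphics::plot(x$field, x$intensity, type = "l",
                 xlab = "Magnetic field [mT]",
                 ylab = "dA/dB [a.u.]", ...)
  invisible(x)
}

#' Parameter bounds for spectral fitting
#'
#' Lower/upper box bounds for each domain parameter, used by the fit and to
#' normalize parameter coordinates in GHOST space.
#'
#' @param S,tau_c,pA,pg,W,d numeric length-2 \code{c(lower, upper)} bounds.
#'   tau_c and W are in ns and mT respectively.
#' @return An object of class \code{fit_bounds}: a named list of
#'   \code{c(lower, upper)} pairs.
#' @export
fit_bounds <- function(S = c(0, 1), tau_c = c(0.05, 5), pA = c(0.85, 1.15),
                       pg = c(0.999, 1.001), W = c(0, 0.5), d = c(0, 1)) {
  b <- list(S = S, tau_c = tau_c, pA = pA, pg = pg, W = W, d = d)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2 || !is.numeric(v) || anyNA(v) || v[1] >= v[2])
      stop("bounds for ", nm, " must be c(lower, upper) with lower < upper")
    b[[nm]] <- as.numeric(v)
  }
  structure(b, class = "fit_bounds")
}
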