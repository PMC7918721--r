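## Pipeline orchestration: declarative config, deterministic seed fan-out,
## and an end-to-end run writing JSON/CSV artifacts.

# One global seed fans out to per-stage seeds: stage_seed =
# (seed * 7919 + stage_index) mod 2^31 - 1 (7919 = 1000th prime; keeps every
# derived seed a valid 32-bit integer and distinct across stages).
#' Derive a stage seed from the pipeline seed
#'
#' @param seed global pipeline seed (integer).
#' @param stage_index integer stage offset (0 = synthesis, 1 = fitting, ...).
#' @return Derived integer seed.
#' @export
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + stage_index) %% (2^31 - 1))
}

#' Pipeline configuration
#'
#' Declarative description of one end-to-end analysis: the input spectrum
#' (a file path or a preset name to synthesize), the fit setup and the GHOST
#' thresholds.  Validated on construction; round-trips losslessly through
#' JSON.
#'
#' @param spectrum_path path to a two-column spectrum file, or `NULL` to
#'   synthesize from `preset`.
#' @param preset preset name for synthetic input (see [make_preset()]).
#' @param snr signal-to-noise ratio for synthetic input.
#' @param K number of spectral components to fit.
#' @param n_runs number of independent HEO runs (>= 1).
#' @param seed global pipeline seed; stage seeds derive via [stage_seed()].
#' @param bounds a [fit_bounds()].
#' @param heo an [heo_config()].
#' @param ghost named list of GHOST thresholds (entries
#'   `fit_keep_fraction`, `fit_margin`, `density_radius`, `min_neighbors`,
#'   `slice_width`, `slice_step`, `link_radius`); unset entries use the
#'   [ghost_condense()] defaults.
#' @param n_theta powder quadrature size for the forward model.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(spectrum_path = NULL, preset = "aT3", snr = 50,
                            K = 3L, n_runs = 200L, seed = 1L,
                            bounds = fit_bounds(), heo = heo_config(),
                            ghost = list(), n_theta = 64L) {
  stopifnot(inherits(bounds, "fit_bounds"), inherits(heo, "heo_config"))
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (K < 1 || K > 5) stop("K must be between 1 and 5")
  if (!is.null(spectrum_path) && !file.exists(spectrum_path))
    stop("spectrum file not found: ", spectrum_path)
  known <- c("fit_keep_fraction", "fit_margin", "density_radius",
             "min_neighbors",
             "slice_width", "slice_step", "link_radius")
  bad <- setdiff(names(ghost), known)
  if (length(bad)) stop("unknown ghost threshold(s): ",
                        paste(bad, collapse = ", "))
  structure(list(spectrum_path = spectrum_path, preset = preset, snr = snr,
                 K = as.integer(K), n_runs = as.integer(n_runs),
                 seed = as.integer(seed), bounds = bounds, heo = heo,
                 ghost = ghost, n_theta = as.integer(n_theta)),
            class = "pipeline_config")
}

# config fingerprint for artifact stamping: md5 of the canonical JSON
.config_hash <- function(config) {
  js <- jsonlite::toJSON(list(
    spectrum_path = config$spectrum_path, preset = config$preset,
    snr = config$snr, K = config$K, n_runs = config$n_runs,
    seed = config$seed, bounds = unclass(config$bounds),
    heo = unclass(config$heo), ghost = config$ghost,
    n_theta = config$n_theta), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Reads (or synthesizes) the input spectrum, runs the multi-run HEO fit,
#' condenses the solution cloud with GHOST, and writes the artifacts to
#' `out_dir`: `spectrum.txt` (+ sidecar), `cloud.json`, `groups.json`, and
#' one `diagram_<axes>.csv` per GHOST projection.  All artifacts are stamped
#' with the config hash and package version; given the same config the
#' serialized artifacts are identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and returns the in-memory artifacts only.
#' @param quiet suppress per-stage progress messages.
#' @return List with `spectrum`, `cloud`, `groups`, `diagrams`, `log`
#'   (per-stage timings and filter counts), `config_hash`, `version`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- .config_hash(config)
  version <- as.character(utils::packageVersion("ghostepr"))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))

  t0 <- tic()
  spectrum <- tryCatch({
    if (!is.null(config$spectrum_path)) {
      read_spectrum(config$spectrum_path)
    } else {
      generate_spectrum(make_preset(config$preset), snr = config$snr,
                        seed = stage_seed(config$seed, 0),
                        n_theta = config$n_theta)
    }
  }, error = function(e) stop("stage 'input' failed: ", conditionMessage(e)))
  log$input <- list(elapsed = tic() - t0, n_points = length(spectrum$field))
  say("input: %d points (%.2fs)", length(spectrum$field), log$input$elapsed)

  t0 <- tic()
  cloud <- tryCatch(
    multi_run(spectrum, K = config$K, bounds = config$bounds,
              n_runs = config$n_runs,
              base_seed = stage_seed(config$seed, 1),
              config = config$heo, n_theta = config$n_theta),
    error = function(e) stop("stage 'fit' failed: ", conditionMessage(e)))
  log$fit <- list(elapsed = tic() - t0, n_runs = config$n_runs)
  say("fit: %d HEO runs (%.1fs)", config$n_runs, log$fit$elapsed)

  t0 <- tic()
  groups <- tryCatch(
    do.call(ghost_condense, c(list(cloud = cloud), config$ghost)),
    error = function(e) stop("stage 'ghost' failed: ", conditionMessage(e)))
  pts <- attr(groups, "points")
  log$ghost <- c(list(elapsed = tic() - t0), attr(pts, "filter"),
                 list(n_groups = length(groups)))
  say("ghost: %d group(s) from %d retained points (%.2fs)",
      length(groups), nrow(pts), log$ghost$elapsed)

  diagrams <- lapply(setNames(nm = c("S-tauc", "S-W", "S-pA")),
                     function(ax) make_diagram(pts, ax))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- list(config_hash = hash, version = version)
    write_spectrum(spectrum, file.path(out_dir, "spectrum.txt"))
    write_cloud(cloud, file.path(out_dir, "cloud.json"))
    write_groups(groups, file.path(out_dir, "groups.json"))
    for (ax in names(diagrams)) {
      fn <- file.path(out_dir,
                      sprintf("diagram_%s.csv", gsub("-", "_", ax)))
      utils::write.csv(as.data.frame(diagrams[[ax]]), fn, row.names = FALSE)
    }
    jsonlite::write_json(c(stamp, list(log = log)),
                         file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(spectrum = spectrum, cloud = cloud, groups = groups,
       diagrams = diagrams, log = log, config_hash = hash,
       version = version)
}
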