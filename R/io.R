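## Spectrum ASCII dialect (two columns: field mT, intensity; '#' headers;
## optional JSON sidecar with spectrometer settings) and JSON serialization
## of solution clouds, domain groups and comparison tables.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a spectrum to a two-column ASCII file
#'
#' Writes `field intensity` rows ('#'-prefixed header lines first) and, by
#' default, a JSON sidecar `<path>.json` holding the spectrometer settings
#' and provenance.
#'
#' @param spectrum an [epr_spectrum()].
#' @param path output file path.
#' @param dialect `"ascii2col"` (whitespace) or `"csv"` (comma).
#' @param sidecar also write the JSON settings sidecar.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, dialect = c("ascii2col", "csv"),
                           sidecar = TRUE) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else " "
  hdr <- c("# EPR first-derivative spectrum",
           sprintf("# columns%sfield_mT%sintensity", sep, sep),
           sprintf("# n_points %d", length(spectrum$field)))
  rows <- paste(format(spectrum$field, digits = 15, trim = TRUE),
                format(spectrum$intensity, digits = 15, trim = TRUE),
                sep = sep)
  writeLines(c(hdr, rows), path)
  if (sidecar) {
    meta <- list(settings = unclass(spectrum$settings),
                 provenance = spectrum$provenance)
    jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a spectrum from a two-column ASCII/CSV file
#'
#' Parses '#'-headed two-column files (field mT, intensity), attaching the
#' JSON sidecar's spectrometer settings when present.  Non-numeric rows,
#' missing columns and non-monotone field grids are reported with line
#' numbers.
#'
#' @param path input file path.
#' @param dialect `"auto"` (default; detects commas), `"ascii2col"` or
#'   `"csv"`.
#' @param min_rows minimum number of data rows required (default 128).
#' @return An [epr_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "ascii2col", "csv"),
                          min_rows = 128L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) < min_rows)
    stop("spectrum file has ", length(data_lines), " data rows; need >= ",
         min_rows)
  split_re <- switch(dialect,
                     auto = "[,\\s]+",
                     ascii2col = "\\s+",
                     csv = "\\s*,\\s*")
  parts <- strsplit(trimws(data_lines), split_re, perl = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad))
    stop("line ", line_no[bad[1]], ": expected two columns")
  field <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  nn <- which(is.na(field) | is.na(intensity))
  if (length(nn))
    stop("line ", line_no[nn[1]], ": non-numeric value")
  nonmono <- which(diff(field) <= 0)
  if (length(nonmono))
    stop("line ", line_no[nonmono[1] + 1],
         ": field is not strictly increasing")
  settings <- spectrometer_settings()
  provenance <- list(source = path)
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$settings))
      settings <- do.call(spectrometer_settings,
                          meta$settings[names(meta$settings) %in%
                                          names(formals(spectrometer_settings))])
    if (!is.null(meta$provenance))
      provenance <- c(provenance, as.list(meta$provenance))
  }
  epr_spectrum(field, intensity, settings, provenance)
}

.schema_version <- "1"

#' Write a solution cloud to JSON
#'
#' @param cloud a `solution_cloud` from [multi_run()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "solution_cloud"))
  obj <- list(schema_version = .schema_version,
              spectrum_id = cloud$spectrum_id,
              K = cloud$K, n_runs = cloud$n_runs,
              base_seed = cloud$base_seed,
              n_points = cloud$n_points,
              bounds = unclass(cloud$bounds),
              solutions = lapply(cloud$solutions, function(s)
                list(chi2 = s$chi2, seed = s$seed, n_evals = s$n_evals,
                     domains = lapply(s$domains, unclass))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a solution cloud from JSON
#'
#' @param path JSON file written by [write_cloud()].
#' @return A `solution_cloud`.
#' @export
read_cloud <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != .schema_version)
    stop("unsupported solution-cloud schema: ", obj$schema_version)
  solutions <- lapply(obj$solutions, function(s) {
    domains <- lapply(s$domains, function(d) do.call(domain_params, d))
    ds <- vapply(domains, `[[`, 0, "d")
    domains[[length(domains)]]$d <- domains[[length(domains)]]$d + (1 - sum(ds))
    structure(list(domains = domains, chi2 = s$chi2,
                   seed = as.integer(s$seed),
                   n_evals = as.integer(s$n_evals),
                   K = length(domains)),
              class = "fit_solution")
  })
  structure(list(solutions = solutions, spectrum_id = obj$spectrum_id,
                 bounds = do.call(fit_bounds, lapply(obj$bounds, unlist)),
                 K = as.integer(obj$K), n_runs = as.integer(obj$n_runs),
                 base_seed = as.integer(obj$base_seed),
                 n_points = if (is.null(obj$n_points)) NULL else
                   as.integer(obj$n_points)),
            class = "solution_cloud")
}

#' Write GHOST groups to JSON
#'
#' @param groups a `ghost_groups` from [ghost_condense()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "ghost_groups"))
  obj <- list(schema_version = .schema_version,
              settings = attr(groups, "settings"),
              groups = lapply(groups, function(g)
                list(label = g$label, n_members = g$n_members,
                     members = g$members,
                     mean = as.list(g$mean), se = as.list(g$se),
                     proportion = g$proportion)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GHOST groups from JSON
#'
#' Restores the group summaries written by [write_groups()] (hulls and the
#' retained point table are not round-tripped).
#'
#' @param path JSON file written by [write_groups()].
#' @return A `ghost_groups` object.
#' @export
read_groups <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  groups <- lapply(obj$groups, function(g)
    structure(list(label = g$label, n_members = g$n_members,
                   members = unlist(g$members),
                   mean = unlist(g$mean), se = unlist(g$se),
                   proportion = g$proportion, hull = NULL),
              class = "ghost_group"))
  structure(groups, class = "ghost_groups",
            settings = obj$settings)
}

#' Write a comparison table to CSV
#'
#' @param table a `comparison_table` from [compare_conditions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path) {
  stopifnot(inherits(table, "comparison_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
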