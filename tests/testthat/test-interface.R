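test_that("spectrum files round-trip losslessly in both dialects", {
  pre <- make_preset("aT3")
  sp <- generate_spectrum(pre, snr = 40, seed = 8)
  for (dialect in c("ascii2col", "csv")) {
    path <- tempfile(fileext = ".txt")
    write_spectrum(sp, path, dialect = dialect)
    back <- read_spectrum(path)
    expect_equal(back$field, sp$field, tolerance = 1e-12)
    expect_equal(back$intensity, sp$intensity, tolerance = 1e-12)
    # sidecar restores the acquisition settings
    expect_equal(back$settings$microwave_frequency,
                 sp$settings$microwave_frequency)
    expect_equal(back$settings$n_points, sp$settings$n_points)
    unlink(c(path, paste0(path, ".json")))
  }
})

test_that("comma and whitespace dialects of the same data parse identically", {
  f <- seq(330, 350, length.out = 200)
  y <- sin(f)
  p1 <- tempfile(); p2 <- tempfile()
  writeLines(c("# header", paste(f, y)), p1)
  writeLines(c("# header", paste(f, y, sep = ",")), p2)
  s1 <- read_spectrum(p1)
  s2 <- read_spectrum(p2)
  expect_identical(s1$field, s2$field)
  expect_identical(s1$intensity, s2$intensity)
  unlink(c(p1, p2))
})

test_that("malformed spectrum files fail with line numbers", {
  f <- seq(330, 350, length.out = 200)
  y <- sin(f)
  # descending field
  p <- tempfile()
  writeLines(paste(rev(f), y), p)
  expect_error(read_spectrum(p), "not strictly increasing")
  # non-numeric row
  lines <- paste(f, y)
  lines[50] <- "330.5 oops"
  writeLines(lines, p)
  expect_error(read_spectrum(p), "line 50")
  # missing column
  lines <- paste(f, y)
  lines[7] <- "331.0"
  writeLines(lines, p)
  expect_error(read_spectrum(p), "line 7")
  # too short
  writeLines(paste(f[1:20], y[1:20]), p)
  expect_error(read_spectrum(p), "data rows")
  unlink(p)
})

test_that("solution clouds and groups survive a JSON round trip", {
  centers <- three_cluster_centers()
  cl <- synthetic_cloud(centers, n_runs = 12, seed = 10)
  pc <- tempfile(fileext = ".json")
  write_cloud(cl, pc)
  back <- read_cloud(pc)
  expect_equal(back$K, cl$K)
  expect_equal(back$n_runs, cl$n_runs)
  expect_equal(
    vapply(back$solutions, function(s) s$chi2, 0),
    vapply(cl$solutions, function(s) s$chi2, 0))
  expect_equal(back$solutions[[3]]$domains[[2]]$S,
               cl$solutions[[3]]$domains[[2]]$S, tolerance = 1e-12)
  expect_equal(unclass(back$bounds), unclass(cl$bounds))

  gr <- ghost_condense(cl)
  pg <- tempfile(fileext = ".json")
  write_groups(gr, pg)
  gback <- read_groups(pg)
  expect_length(gback, length(gr))
  expect_equal(vapply(gback, function(g) unname(g$mean["S"]), 0),
               vapply(gr, function(g) unname(g$mean["S"]), 0),
               tolerance = 1e-12)
  expect_equal(vapply(gback, function(g) g$proportion, 0),
               vapply(gr, function(g) g$proportion, 0), tolerance = 1e-12)
  unlink(c(pc, pg))
})

test_that("pipeline configs validate before any compute", {
  expect_error(pipeline_config(n_runs = 0), "n_runs")
  expect_error(pipeline_config(K = 9), "K must be")
  expect_error(pipeline_config(spectrum_path = "/nonexistent/x.txt"),
               "not found")
  expect_error(pipeline_config(ghost = list(bogus = 1)), "unknown ghost")
})

test_that("the pipeline is deterministic given config and seeds", {
  cfg <- pipeline_config(preset = "aT3", snr = 40, K = 2, n_runs = 6,
                         seed = 3,
                         heo = heo_config(population = 16, generations = 4,
                                          nm_maxit = 150, nm_restarts = 1),
                         ghost = list(fit_keep_fraction = 1,
                                      min_neighbors = 0))
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  r1 <- run_pipeline(cfg, out_dir = d1, quiet = TRUE)
  r2 <- run_pipeline(cfg, out_dir = d2, quiet = TRUE)
  for (f in c("spectrum.txt", "cloud.json", "groups.json",
              "diagram_S_tauc.csv", "diagram_S_W.csv", "diagram_S_pA.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_identical(r1$config_hash, r2$config_hash)
  expect_s3_class(r1$groups, "ghost_groups")
  expect_true(all(c("input", "fit", "ghost") %in% names(r1$log)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("stage seeds derive deterministically and stay 32-bit", {
  s <- vapply(0:5, function(i) stage_seed(123, i), 0L)
  expect_identical(s, vapply(0:5, function(i) stage_seed(123, i), 0L))
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(any(duplicated(s)))
  expect_true(all(vapply(0:5, function(i)
    stage_seed(2147483647, i), 0L) < 2^31))
})

test_that("the CLI exposes every subcommand in its help text", {
  cli <- system.file("cli", "ghostepr.R", package = "ghostepr")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli, "--help"),
                                  stdout = TRUE, stderr = TRUE))
  for (sub in c("simulate", "fit", "ghost", "compare", "synth", "run"))
    expect_true(any(grepl(sub, out)), label = sub)
  # validation errors exit with status 2
  bad <- suppressWarnings(system2(rscript, c(cli, "synth", "--preset", "HeLa",
                                             "--out", tempfile()),
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2L)
})
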