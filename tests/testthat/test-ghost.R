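test_that("goodness-of-fit filter keeps the best runs and explodes them", {
  centers <- three_cluster_centers()
  cl <- synthetic_cloud(centers, n_runs = 40, seed = 1)
  pts <- filter_solutions(cl)
  # default keep fraction 0.5: 20 runs x 3 components
  expect_equal(nrow(pts), 60)
  expect_s3_class(pts, "ghost_points")

  # a run with chi2 1000x the best is dropped by the fit filter
  chi2 <- c(rep(1, 39), 1000)
  cl2 <- synthetic_cloud(centers, n_runs = 40, seed = 1, chi2 = chi2)
  pts2 <- filter_solutions(cl2)
  expect_false(40 %in% pts2$run)

  # identical solutions: everything retained
  cl3 <- synthetic_cloud(centers, n_runs = 10, sd = 0, seed = 1,
                         chi2 = rep(1, 10))
  pts3 <- filter_solutions(cl3, fit_keep_fraction = 1)
  expect_equal(nrow(pts3), 30)
})

test_that("density filter removes isolated points (brute-force oracle)", {
  centers <- three_cluster_centers()
  # one archetype run placed far away in parameter space
  cl <- synthetic_cloud(centers, n_runs = 41, seed = 2,
                        chi2 = rep(1, 41))
  # move run 41's domain 2 to an isolated spot
  cl$solutions[[41]]$domains[[2]]$S <- 0.85
  cl$solutions[[41]]$domains[[2]]$tau_c <- 4.5
  pts_all <- filter_solutions(cl, fit_keep_fraction = 1, min_neighbors = 0)
  X <- as.matrix(pts_all[, c("nS", "ntau_c", "nW", "npA")])
  nb <- brute_neighbor_counts(X, 0.05)
  pts <- filter_solutions(cl, fit_keep_fraction = 1,
                          density_radius = 0.05, min_neighbors = 5)
  expect_setequal(which(nb >= 5), which(
    paste(pts_all$run, pts_all$component) %in%
      paste(pts$run, pts$component)))
  # the isolated point is gone
  expect_false(any(pts$run == 41 & pts$component == 2))
  # filtering everything out is an explicit error
  expect_error(filter_solutions(cl, min_neighbors = 1000),
               "no condensable solutions")
})

test_that("slicing detects the planted number of groups", {
  centers <- three_cluster_centers()
  cl <- synthetic_cloud(centers, n_runs = 40, seed = 3)
  pts <- filter_solutions(cl)
  groups <- detect_groups(pts)
  expect_length(groups, 3)
  # single cluster is a legal single group
  one <- synthetic_cloud(centers[2, , drop = FALSE], n_runs = 30, seed = 4)
  gp1 <- detect_groups(filter_solutions(one))
  expect_length(gp1, 1)
  # membership is a partition
  expect_setequal(unlist(groups), seq_len(nrow(pts)))
})

test_that("group detection equals brute-force slice-linkage components", {
  set.seed(7)
  for (rep in 1:5) {
    K <- sample(2:3, 1)
    centers <- three_cluster_centers()[seq_len(K), , drop = FALSE]
    cl <- synthetic_cloud(centers, n_runs = sample(20:60, 1),
                          sd = runif(1, 0.003, 0.02), seed = rep)
    pts <- filter_solutions(cl, min_neighbors = 2)
    expect_lte(nrow(pts), 500)
    groups <- detect_groups(pts, link_radius = 0.05)
    comp <- brute_slice_components(
      pts$nS, as.matrix(pts[, c("ntau_c", "nW", "npA")]),
      slice_width = 0.05, slice_step = 0.025, radius = 0.05)
    # same partition (labels may differ)
    impl <- integer(nrow(pts))
    for (g in seq_along(groups)) impl[groups[[g]]] <- g
    expect_equal(length(unique(comp)), length(groups))
    cross <- table(impl, comp)
    expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))
  }
})

test_that("group detection is deterministic and order-invariant", {
  centers <- three_cluster_centers()
  cl <- synthetic_cloud(centers, n_runs = 30, seed = 5)
  pts <- filter_solutions(cl)
  g1 <- detect_groups(pts)
  g2 <- detect_groups(pts)
  expect_identical(g1, g2)
  # shuffle rows: same partition of the same points
  perm <- sample(nrow(pts))
  pts_sh <- pts[perm, ]
  attr(pts_sh, "bounds") <- attr(pts, "bounds")
  g3 <- detect_groups(pts_sh)
  key1 <- vapply(g1, function(m)
    paste(sort(paste(pts$run[m], pts$component[m])), collapse = "|"), "")
  key3 <- vapply(g3, function(m)
    paste(sort(paste(pts_sh$run[m], pts_sh$component[m])), collapse = "|"), "")
  expect_setequal(key1, key3)
})

test_that("group summaries report means, errors and renormalized proportions", {
  centers <- three_cluster_centers()
  # members all identical -> zero standard errors
  cl0 <- synthetic_cloud(centers, n_runs = 12, sd = 0, seed = 6,
                         chi2 = rep(1, 12))
  pts0 <- filter_solutions(cl0, fit_keep_fraction = 1)
  g0 <- detect_groups(pts0)
  s0 <- group_summary(g0[[1]], pts0, label = 1)
  expect_equal(unname(s0$se), rep(0, 4))

  # proportions renormalize to 100 across groups
  two <- centers[1:2, , drop = FALSE]
  cl2 <- synthetic_cloud(two, n_runs = 20, seed = 7, d = c(0.6, 0.4))
  gr <- ghost_condense(cl2, min_neighbors = 2)
  props <- vapply(gr, function(g) g$proportion, 0)
  expect_equal(sum(props), 100, tolerance = 1e-9)
  expect_equal(props, c(60, 40), tolerance = 2)

  # planted three-cluster cloud: group means within 1 planted sd of centers
  cl3 <- synthetic_cloud(centers, n_runs = 40, sd = 0.01, seed = 8)
  gr3 <- ghost_condense(cl3)
  expect_length(gr3, 3)
  for (i in 1:3) {
    expect_lt(abs(gr3[[i]]$mean["S"] - centers[i, "S"]), 0.01)
    expect_lt(abs(gr3[[i]]$mean["tau_c"] - centers[i, "tau_c"]), 0.05)
  }
  # labels ordered by descending mean S
  Ss <- vapply(gr3, function(g) unname(g$mean["S"]), 0)
  expect_true(all(diff(Ss) < 0))
})

test_that("three separated Gaussian clusters are recovered in >= 95% of replicates", {
  centers <- three_cluster_centers()
  hits <- 0
  for (r in 1:100) {
    cl <- synthetic_cloud(centers, n_runs = 30, sd = 0.008, seed = 1000 + r)
    gr <- tryCatch(ghost_condense(cl), error = function(e) NULL)
    if (!is.null(gr) && length(gr) == 3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("diagrams project retained points with RGB parameter encoding", {
  centers <- three_cluster_centers()
  cl <- synthetic_cloud(centers, n_runs = 20, seed = 9)
  pts <- filter_solutions(cl)
  for (ax in c("S-tauc", "S-W", "S-pA")) {
    dg <- make_diagram(pts, ax)
    expect_equal(nrow(dg), nrow(pts))
    expect_identical(dg, make_diagram(pts, ax))
  }
  dg <- make_diagram(pts, "S-tauc")
  expect_equal(dg$y, pts$tau_c)
  expect_error(make_diagram(pts, "tauc-W"))

  # point at tau_c upper bound, W and pA at lower bounds -> pure red
  b <- fit_bounds()
  cl1 <- synthetic_cloud(rbind(c(S = 0.5, tau_c = b$tau_c[2],
                                 pA = b$pA[1], W = b$W[1])),
                         n_runs = 10, sd = 0, seed = 1, chi2 = rep(1, 10))
  p1 <- filter_solutions(cl1, fit_keep_fraction = 1)
  d1 <- make_diagram(p1, "S-tauc")
  expect_equal(d1$r[1], 1)
  expect_equal(d1$g[1], 0)
  expect_equal(d1$b[1], 0)
  expect_equal(d1$color[1], "#FF0000")
})
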