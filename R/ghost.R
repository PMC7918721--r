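## GHOST condensation: filter the multi-run solution cloud by goodness of
## fit and local density in normalized parameter space, detect domain groups
## by an overlapping-slice procedure along the order-parameter axis, and
## summarize each group.

.ghost_coord_names <- c("S", "tau_c", "W", "pA")

.normalize_points <- function(df, bounds) {
  for (p in .ghost_coord_names) {
    lo <- bounds[[p]][1]; hi <- bounds[[p]][2]
    df[[paste0("n", p)]] <- (df[[p]] - lo) / (hi - lo)
  }
  df
}

#' Filter a solution cloud for condensation
#'
#' Three-stage filter: (1) keep the runs whose chi-square is both within
#' the best `fit_keep_fraction` of all runs (ties kept) and within
#' `fit_margin` standard deviations of the best run's chi-square — for a
#' correctly scaled fit the chi-square statistic has sd ~ sqrt(2 N), and
#' the margin is self-scaled as `chi2_min (1 + fit_margin sqrt(2/N))` so a
#' misestimated noise level cancels; (2) explode every kept run into K
#' points, one per fitted domain, with coordinates (S, tau_c, W, pA)
#' normalized to \[0,1\] by the fit bounds; (3) drop points with fewer than
#' `min_neighbors` other points within `density_radius` (Euclidean, in the
#' normalized 4-D space).
#'
#' @param cloud a `solution_cloud` from [multi_run()].
#' @param fit_keep_fraction fraction of runs retained by chi-square rank.
#' @param fit_margin goodness-of-fit margin in chi-square standard
#'   deviations above the best run; `Inf` disables the margin.
#' @param density_radius neighborhood radius in normalized coordinates.
#' @param min_neighbors minimum neighbor count (excluding the point itself).
#' @return A `ghost_points` data frame (one row per retained domain point)
#'   with raw and normalized coordinates, fitted proportion `d`, run index
#'   and chi-square; filter settings and bounds are attached as attributes.
#' @export
filter_solutions <- function(cloud, fit_keep_fraction = 0.5,
                             fit_margin = 1, density_radius = 0.1,
                             min_neighbors = 3L) {
  stopifnot(inherits(cloud, "solution_cloud"),
            fit_keep_fraction > 0, fit_keep_fraction <= 1,
            fit_margin > 0, density_radius > 0, min_neighbors >= 0)
  chi2 <- vapply(cloud$solutions, `[[`, 0, "chi2")
  n_keep <- max(1L, ceiling(fit_keep_fraction * length(chi2)))
  rank_thr <- sort(chi2)[n_keep]
  margin_thr <- if (is.finite(fit_margin) && !is.null(cloud$n_points)) {
    min(chi2) * (1 + fit_margin * sqrt(2 / cloud$n_points))
  } else {
    Inf
  }
  kept_runs <- which(chi2 <= rank_thr & chi2 <= margin_thr)

  rows <- lapply(kept_runs, function(i) {
    sol <- cloud$solutions[[i]]
    do.call(rbind, lapply(seq_along(sol$domains), function(k) {
      dm <- sol$domains[[k]]
      data.frame(run = i, component = k, chi2 = sol$chi2,
                 S = dm$S, tau_c = dm$tau_c, W = dm$W, pA = dm$pA,
                 pg = dm$pg, d = dm$d)
    }))
  })
  pts <- do.call(rbind, rows)
  pts <- .normalize_points(pts, cloud$bounds)

  X <- as.matrix(pts[, paste0("n", .ghost_coord_names)])
  D <- as.matrix(stats::dist(X))
  n_nb <- rowSums(D <= density_radius) - 1L
  keep <- n_nb >= min_neighbors
  if (!any(keep))
    stop("no condensable solutions: every point failed the density filter ",
         "(radius ", density_radius, ", min_neighbors ", min_neighbors, ")")
  pts <- pts[keep, , drop = FALSE]
  rownames(pts) <- NULL
  structure(pts, class = c("ghost_points", "data.frame"),
            bounds = cloud$bounds,
            filter = list(fit_keep_fraction = fit_keep_fraction,
                          fit_margin = fit_margin,
                          density_radius = density_radius,
                          min_neighbors = as.integer(min_neighbors),
                          runs_kept = length(kept_runs),
                          points_kept = sum(keep),
                          points_total = length(keep)))
}

.unionfind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  list(find = find,
       union = function(i, j) {
         ri <- find(i); rj <- find(j)
         if (ri != rj) parent[ri] <<- rj
       },
       roots = function() vapply(seq_len(n), find, 0L))
}

# slice starts shared by detect_groups and the documentation of the
# equivalent pairwise linkage rule: points i, j are linked iff some slice
# [s, s + width] contains both normalized S values and their distance in
# the normalized (tau_c, W, pA) subspace is <= link_radius.
.slice_starts <- function(slice_step) seq(0, 1, by = slice_step)

#' Detect domain groups by slicing along the order parameter
#'
#' The normalized S axis is covered with overlapping slices of width
#' `slice_width` advanced by `slice_step`.  Within each slice, points whose
#' distance in the normalized (tau_c, W, pA) subspace is at most
#' `link_radius` are linked; links are accumulated across slices, so
#' clusters sharing points in overlapping slices merge.  The final groups
#' are the connected components, ordered by descending mean order parameter
#' and labelled domain 1, 2, 3, ...  The procedure consumes no randomness
#' and is invariant to point order.
#'
#' @param points a `ghost_points` object from [filter_solutions()].
#' @param slice_width slice width on the normalized S axis.
#' @param slice_step slice advance step (overlap = width - step).
#' @param link_radius linkage radius in the normalized 3-D subspace.
#' @return List of integer vectors, one per group, each holding the row
#'   indices of the group's member points (sorted), ordered by descending
#'   mean S.
#' @export
detect_groups <- function(points, slice_width = 0.05, slice_step = 0.025,
                          link_radius = 0.1) {
  stopifnot(inherits(points, "ghost_points"), nrow(points) >= 1,
            slice_width > 0, slice_step > 0, link_radius > 0)
  n <- nrow(points)
  uf <- .unionfind(n)
  nS <- points$nS
  Y <- as.matrix(points[, c("ntau_c", "nW", "npA")])
  for (s in .slice_starts(slice_step)) {
    idx <- which(nS >= s & nS <= s + slice_width)
    if (length(idx) < 2) next
    D <- as.matrix(stats::dist(Y[idx, , drop = FALSE]))
    pairs <- which(D <= link_radius & upper.tri(D), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs)))
      uf$union(idx[pairs[r, 1]], idx[pairs[r, 2]])
  }
  roots <- uf$roots()
  members <- split(seq_len(n), roots)
  meanS <- vapply(members, function(m) mean(points$S[m]), 0)
  members <- members[order(meanS, decreasing = TRUE)]
  names(members) <- NULL
  lapply(members, sort)
}

#' Summarize one GHOST group
#'
#' Per-parameter mean over the member points, standard errors from the
#' diagonal of the member covariance matrix (sd / sqrt(n), the between-run
#' spread of the condensed solutions), and the group's raw proportion (mean
#' fitted `d`, in percent, before cross-group renormalization).  Singleton
#' groups report means with `NA` standard errors.
#'
#' @param members integer row indices into `points`.
#' @param points the parent `ghost_points`.
#' @param label group label (1 = highest order parameter).
#' @return A `ghost_group` list: `label`, `n_members`, `members`, `mean`,
#'   `se`, `proportion` (percent, unnormalized), `hull` (convex hull
#'   coordinates in the S-tau_c, S-W and S-pA projections).
#' @export
group_summary <- function(members, points, label = NA_integer_) {
  stopifnot(inherits(points, "ghost_points"), length(members) >= 1)
  sub <- points[members, , drop = FALSE]
  pars <- c("S", "tau_c", "pA", "W")
  m <- vapply(pars, function(p) mean(sub[[p]]), 0)
  se <- if (nrow(sub) >= 2) {
    cv <- stats::cov(as.matrix(sub[, pars]))
    sqrt(diag(cv) / nrow(sub))
  } else {
    setNames(rep(NA_real_, length(pars)), pars)
  }
  hull <- lapply(c(tau_c = "tau_c", W = "W", pA = "pA"), function(p) {
    xy <- cbind(S = sub$S, sub[[p]])
    colnames(xy) <- c("S", p)
    xy[grDevices::chull(xy), , drop = FALSE]
  })
  structure(list(label = label, n_members = length(members),
                 members = members, mean = m, se = se,
                 proportion = 100 * mean(sub$d), hull = hull),
            class = "ghost_group")
}

#' @export
print.ghost_group <- function(x, ...) {
  cat(sprintf(
    "domain %s: S = %.3f (se %.3g), tau_c = %.3g ns (se %.3g), d = %.1f%%, %d points\n",
    x$label, x$mean["S"], x$se["S"], x$mean["tau_c"], x$se["tau_c"],
    x$proportion, x$n_members))
  invisible(x)
}

#' Condense a solution cloud into domain groups
#'
#' Full GHOST procedure: [filter_solutions()], [detect_groups()], then
#' [group_summary()] per group with proportions renormalized so they sum to
#' 100% across groups.  Groups are labelled by descending mean order
#' parameter (domain 1 = most ordered).
#'
#' @param cloud a `solution_cloud`.
#' @param fit_keep_fraction,fit_margin,density_radius,min_neighbors see
#'   [filter_solutions()].
#' @param slice_width,slice_step,link_radius see [detect_groups()].
#' @return A `ghost_groups` object: list of `ghost_group`s with the retained
#'   `ghost_points` and the threshold settings attached as attributes.
#' @export
ghost_condense <- function(cloud, fit_keep_fraction = 0.5, fit_margin = 1,
                           density_radius = 0.1, min_neighbors = 3L,
                           slice_width = 0.05, slice_step = 0.025,
                           link_radius = density_radius) {
  pts <- filter_solutions(cloud, fit_keep_fraction, fit_margin,
                          density_radius, min_neighbors)
  members <- detect_groups(pts, slice_width, slice_step, link_radius)
  groups <- Map(function(m, lab) group_summary(m, pts, label = lab),
                members, seq_along(members))
  raw <- vapply(groups, `[[`, 0, "proportion")
  for (i in seq_along(groups))
    groups[[i]]$proportion <- 100 * raw[i] / sum(raw)
  structure(groups, class = "ghost_groups", points = pts,
            settings = c(attr(pts, "filter"),
                         list(slice_width = slice_width,
                              slice_step = slice_step,
                              link_radius = link_radius)))
}

#' @export
print.ghost_groups <- function(x, ...) {
  cat(sprintf("GHOST condensation: %d domain group(s)\n", length(x)))
  for (g in x) print(g)
  invisible(x)
}

#' Mean order parameter of the intermediate domain type
#'
#' The three-domain model postulates three domain types.  With exactly
#' three groups this is simply the middle group's mean S.  When
#' condensation fragments the solution cloud into more groups (component
#' role-swapping between overlapping domains produces distinct clusters),
#' the groups are assigned to three domain types by the optimal 1-D
#' partition of their mean order parameters (minimizing the
#' proportion-weighted within-type variance of S), and the intermediate
#' type's proportion-weighted mean S is returned.  With fewer than three
#' groups the lower-ranked group's mean S is returned (the domain types
#' could not be resolved).
#'
#' @param groups a `ghost_groups` object (or list of `ghost_group`s).
#' @return The intermediate domain type's mean order parameter (scalar).
#' @export
intermediate_order <- function(groups) {
  S <- vapply(groups, function(g) unname(g$mean["S"]), 0)
  d <- vapply(groups, function(g) g$proportion, 0)
  o <- order(S, decreasing = TRUE)
  S <- S[o]; d <- d[o]
  G <- length(S)
  if (G <= 2) return(S[min(2, G)])
  if (G == 3) return(S[2])
  wvar <- function(idx) {
    w <- d[idx]
    m <- sum(S[idx] * w) / sum(w)
    sum(w * (S[idx] - m)^2)
  }
  best <- NULL
  bestv <- Inf
  for (i in 1:(G - 2)) {
    for (j in (i + 1):(G - 1)) {
      v <- wvar(1:i) + wvar((i + 1):j) + wvar((j + 1):G)
      if (v < bestv) {
        bestv <- v
        best <- c(i, j)
      }
    }
  }
  mid <- (best[1] + 1):best[2]
  sum(S[mid] * d[mid]) / sum(d[mid])
}

#' GHOST diagram point table
#'
#' Two-dimensional cross-section of the retained solution points: the order
#' parameter against one of tau_c, W or pA, with each point's RGB color
#' encoding the remaining parameters (red = tau_c, green = W, blue = pA,
#' each normalized to its fit bounds).
#'
#' @param points a `ghost_points` object.
#' @param axis one of `"S-tauc"`, `"S-W"`, `"S-pA"`.
#' @return A `ghost_diagram` data frame with columns `x` (S), `y`, `r`,
#'   `g`, `b` and a hex `color`; one row per retained point.
#' @export
make_diagram <- function(points, axis = c("S-tauc", "S-W", "S-pA")) {
  stopifnot(inherits(points, "ghost_points"))
  axis <- match.arg(axis)
  ycol <- switch(axis, "S-tauc" = "tau_c", "S-W" = "W", "S-pA" = "pA")
  clamp <- function(v) pmin(1, pmax(0, v))
  r <- clamp(points$ntau_c); g <- clamp(points$nW); b <- clamp(points$npA)
  out <- data.frame(x = points$S, y = points[[ycol]],
                    r = r, g = g, b = b,
                    color = grDevices::rgb(r, g, b))
  structure(out, class = c("ghost_diagram", "data.frame"),
            axis = axis, ylab = ycol)
}

#' @export
plot.ghost_diagram <- function(x, ...) {
  graphics::plot(x$x, x$y, col = x$color, pch = 19,
                 xlab = "order parameter S",
                 ylab = attr(x, "ylab"), main = attr(x, "axis"), ...)
  invisible(x)
}
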