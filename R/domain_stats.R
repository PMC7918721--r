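## Cross-condition comparison of condensed domain groups: rank-based domain
## matching, relative parameter changes with first-order error propagation,
## and replicate-level two-sample t tests.

#' Match domain groups across two conditions
#'
#' Domains are paired by their order-parameter rank: the most ordered group
#' in one condition is matched to the most ordered group in the other, and
#' so on (domain 1 = highest S).  Matching is invariant to the input order
#' of the groups.
#'
#' @param groups_a,groups_b `ghost_groups` objects (or plain lists of
#'   `ghost_group`s) with equal group counts.
#' @return A data frame with one row per matched pair: `domain` (rank
#'   label), `S_a`, `S_b`, and the positions `index_a`, `index_b` into the
#'   input lists.
#' @export
match_domains <- function(groups_a, groups_b) {
  s_of <- function(gs) vapply(gs, function(g) unname(g$mean["S"]), 0)
  sa <- s_of(groups_a); sb <- s_of(groups_b)
  if (length(sa) != length(sb))
    stop("group count mismatch: ", length(sa), " vs ", length(sb),
         " (S values: ", paste(round(sa, 3), collapse = ", "), " vs ",
         paste(round(sb, 3), collapse = ", "), ")")
  oa <- order(sa, decreasing = TRUE); ob <- order(sb, decreasing = TRUE)
  data.frame(domain = seq_along(sa),
             index_a = oa, index_b = ob,
             S_a = sa[oa], S_b = sb[ob])
}

#' Relative change of a parameter between two conditions
#'
#' `(mean(condition) - mean(control)) / mean(control)`, with a standard
#' error from first-order (delta-method) propagation of the two replicate
#' standard errors.
#'
#' @param values_condition,values_control numeric vectors of per-replicate
#'   values (>= 1 each).
#' @return List with `rel_change`, `se` (NA when either side has a single
#'   replicate), `mean_condition`, `mean_control`.
#' @export
relative_change <- function(values_condition, values_control) {
  stopifnot(is.numeric(values_condition), length(values_condition) >= 1,
            is.numeric(values_control), length(values_control) >= 1)
  ma <- mean(values_condition); mc <- mean(values_control)
  if (abs(mc) < .Machine$double.eps)
    stop("control mean is zero; relative change undefined")
  se_a <- if (length(values_condition) > 1)
    stats::sd(values_condition) / sqrt(length(values_condition)) else NA_real_
  se_c <- if (length(values_control) > 1)
    stats::sd(values_control) / sqrt(length(values_control)) else NA_real_
  se <- sqrt(se_a^2 / mc^2 + ma^2 * se_c^2 / mc^4)
  list(rel_change = ma / mc - 1, se = se,
       mean_condition = ma, mean_control = mc)
}

# extract one parameter of one rank-matched domain from a list of
# per-replicate ghost_groups
.replicate_values <- function(replicates, domain_rank, parameter) {
  vapply(replicates, function(gs) {
    s <- vapply(gs, function(g) unname(g$mean["S"]), 0)
    g <- gs[[order(s, decreasing = TRUE)[domain_rank]]]
    if (parameter == "d") g$proportion / 100 else unname(g$mean[parameter])
  }, 0)
}

#' Compare domain parameters across two conditions
#'
#' For every rank-matched domain and every parameter, computes the relative
#' change of the condition vs. the control (means over replicates) and a
#' two-sided two-sample Student's t test on the per-replicate values
#' (equal-variance by default; set `var_equal = FALSE` for Welch).
#' Significance is flagged at p < 0.05; no multiple-testing correction is
#' applied unless `bonferroni = TRUE`.
#'
#' @param replicates_condition,replicates_control lists of `ghost_groups`,
#'   one element per independent replicate; all replicates must contain the
#'   same number of groups.
#' @param parameters parameters to compare (subset of `S`, `tau_c`, `pA`,
#'   `d`; `d` is compared as a fraction).
#' @param var_equal use the equal-variance Student's t test (default).
#' @param bonferroni apply a Bonferroni correction across the table.
#' @return A `comparison_table` data frame with one row per (domain,
#'   parameter): means, `rel_change`, `rel_se`, `t`, `df`, `p`,
#'   `significant`.  With fewer than 2 replicates on either side the test
#'   columns are `NA` and `significant` is `NA` (not computable).
#' @export
compare_conditions <- function(replicates_condition, replicates_control,
                               parameters = c("S", "tau_c", "pA", "d"),
                               var_equal = TRUE, bonferroni = FALSE) {
  stopifnot(length(replicates_condition) >= 1,
            length(replicates_control) >= 1)
  parameters <- match.arg(parameters, c("S", "tau_c", "pA", "d"),
                          several.ok = TRUE)
  counts <- vapply(c(replicates_condition, replicates_control), length, 0L)
  if (length(unique(counts)) != 1)
    stop("replicates disagree on the number of domain groups: ",
         paste(counts, collapse = ", "))
  K <- counts[1]
  testable <- length(replicates_condition) >= 2 &&
    length(replicates_control) >= 2
  rows <- list()
  for (dom in seq_len(K)) {
    for (p in parameters) {
      va <- .replicate_values(replicates_condition, dom, p)
      vc <- .replicate_values(replicates_control, dom, p)
      rc <- relative_change(va, vc)
      if (testable && stats::sd(c(va, vc)) > 0) {
        tt <- stats::t.test(va, vc, var.equal = var_equal)
        t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
        pval <- tt$p.value
      } else if (testable) {
        t_stat <- 0; df <- length(va) + length(vc) - 2; pval <- 1
      } else {
        t_stat <- NA_real_; df <- NA_real_; pval <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        domain = dom, parameter = p,
        mean_condition = rc$mean_condition, mean_control = rc$mean_control,
        rel_change = rc$rel_change, rel_se = rc$se,
        t = t_stat, df = df, p = pval)
    }
  }
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- pmin(1, out$p * nrow(out))
  out$significant <- ifelse(is.na(out$p), NA, out$p < 0.05)
  structure(out, class = c("comparison_table", "data.frame"),
            n_condition = length(replicates_condition),
            n_control = length(replicates_control),
            var_equal = var_equal, bonferroni = bonferroni)
}
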