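#' Group summary: mean and standard error of the mean
#'
#' @param values Numeric vector, `n >= 1`.
#' @param group_id Optional label.
#' @return A `"group_summary"`: `group_id`, `n`, `mean`, `sem`
#'   (sample s.d. with the n-1 denominator over sqrt(n); 0 with a warning
#'   for a single value).
#' @export
group_summary <- function(values, group_id = NA) {
  if (length(values) == 0L) stop("empty group", call. = FALSE)
  n <- length(values)
  sem <- if (n == 1L) {
    warning("SEM undefined for a single value; reporting 0", call. = FALSE)
    0
  } else stats::sd(values) / sqrt(n)
  structure(list(group_id = group_id, n = n, mean = mean(values), sem = sem),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.3g +/- %.2g (mean +/- SEM, n = %d)\n",
              if (is.na(x$group_id)) "group" else as.character(x$group_id),
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Fold change between two group means
#'
#' E.g. normalized viable tumor area 0.47 under flow over 0.18 static
#' gives the 2.6-fold difference; platinum uptake 37788 over 9773 ng/mg
#' protein gives 3.9-fold.
#'
#' @param numerator_mean,denominator_mean Group means; the denominator
#'   must be positive.
#' @return The full-precision ratio, with attribute `reported` rounded to
#'   2 significant figures.
#' @export
fold_change <- function(numerator_mean, denominator_mean) {
  if (denominator_mean <= 0)
    stop("fold change denominator must be positive", call. = FALSE)
  r <- numerator_mean / denominator_mean
  attr(r, "reported") <- signif(r, 2)
  r
}

#' Tumoricidal percentage from a normalized viable area
#'
#' `100 * (1 - x)`: a mean normalized tumor area of 0.18 is an 82%
#' tumoricidal effect. Values above 1 (net growth) give negative
#' percentages.
#'
#' @param normalized_mean Normalized viable tumor area (>= 0).
#' @return Percent reduction.
#' @export
percent_reduction <- function(normalized_mean) {
  if (any(normalized_mean < 0))
    stop("normalized areas must be non-negative", call. = FALSE)
  100 * (1 - normalized_mean)
}

.test_result <- function(test, statistic, p, comparison = NA,
                         adjustment = "none") {
  structure(list(test_name = test, statistic = unname(statistic),
                 p_value = unname(p), comparison = comparison,
                 adjustment = adjustment),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g%s\n", x$test_name, x$statistic,
              x$p_value,
              if (identical(x$adjustment, "none")) ""
              else paste0(" (", x$adjustment, ")")))
  invisible(x)
}

#' Welch two-sample t test (two-tailed)
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return A `"test_result"`. Two constant equal groups give p = 1 by
#'   convention.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t needs n >= 2 per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(.test_result("Welch t", 0, 1, "a vs b"))
    return(.test_result("Welch t", Inf * sign(mean(a) - mean(b)), 0, "a vs b"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  .test_result("Welch t", tt$statistic, tt$p.value, "a vs b")
}

#' Mann-Whitney (Wilcoxon rank-sum) test, two-tailed
#'
#' Uses the exact null distribution for small tie-free samples (both
#' groups n <= 8) and the normal approximation with tie correction
#' otherwise.
#'
#' @param a,b Numeric vectors.
#' @return A `"test_result"` with the U statistic.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && max(length(a), length(b)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  .test_result("Mann-Whitney U", wt$statistic, wt$p.value, "a vs b")
}

#' Monte-Carlo reference distribution for Dunnett-type contrasts
#'
#' Simulates the joint null distribution of the `k - 1` treated-vs-control
#' t statistics (shared control, pooled variance) and returns the draws of
#' \eqn{\max_i |T_i|}, from which single-step adjusted p values follow.
#' Cached per design so repeated calls (e.g. calibration studies) are
#' cheap.
#'
#' @param n_per_group Integer vector of group sizes, control first.
#' @param ndraws Number of Monte-Carlo draws (>= 1e4; default 1e5).
#' @param seed RNG seed for the reference draws.
#' @return Numeric vector of `ndraws` samples of the maximum absolute
#'   contrast t statistic under the null.
#' @export
dunnett_reference <- function(n_per_group, ndraws = 1e5, seed = 20200417L) {
  k <- length(n_per_group)
  stopifnot(k >= 2L, all(n_per_group >= 2L), ndraws >= 1e4)
  df <- sum(n_per_group) - k
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mcontrol <- stats::rnorm(ndraws, 0, 1 / sqrt(n_per_group[1L]))
  s2 <- stats::rchisq(ndraws, df) / df
  maxt <- rep(0, ndraws)
  for (i in 2:k) {
    mi <- stats::rnorm(ndraws, 0, 1 / sqrt(n_per_group[i]))
    ti <- (mi - mcontrol) /
      sqrt(s2 * (1 / n_per_group[i] + 1 / n_per_group[1L]))
    maxt <- pmax(maxt, abs(ti))
  }
  maxt
}

#' One-way ANOVA with Dunnett-style comparisons against a control
#'
#' Reports the one-way ANOVA F test and, for every non-control group, the
#' treated-vs-control t statistic (pooled variance) with a single-step
#' adjusted p value computed from the seeded Monte-Carlo reference
#' distribution of the maximum absolute contrast statistic
#' ([dunnett_reference()]). With `rank = TRUE` the rank-based variant is
#' used instead: Kruskal-Wallis plus Dunn's pairwise z tests against the
#' control with Bonferroni adjustment.
#'
#' @param groups List of numeric vectors (each n >= 2).
#' @param control_index Index of the control group in `groups`.
#' @param ndraws,seed Monte-Carlo settings for the Dunnett reference.
#' @param rank Logical; use Kruskal-Wallis + Dunn instead.
#' @param reference Optional precomputed [dunnett_reference()] draws for
#'   this design (ignored when `rank = TRUE`).
#' @return A list of class `"anova_dunnett"`: `anova` (a `"test_result"`)
#'   and `comparisons`, a data frame with `group`, `statistic`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
anova_dunnett <- function(groups, control_index = 1L, ndraws = 1e5,
                          seed = 20200417L, rank = FALSE, reference = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (control_index < 1L || control_index > length(groups))
    stop("invalid control index", call. = FALSE)
  if (length(groups[[control_index]]) == 0L)
    stop("control group is empty", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  ## put control first
  ord <- c(control_index, setdiff(seq_along(groups), control_index))
  g <- groups[ord]
  labs <- if (!is.null(names(groups))) names(groups)[ord]
          else as.character(ord)
  y <- unlist(g)
  f <- factor(rep(seq_along(g), lengths(g)))
  if (rank) {
    kw <- stats::kruskal.test(y, f)
    cmp <- .dunn_vs_control(y, f)
    cmp$group <- labs[-1L]
    return(structure(list(
      anova = .test_result("Kruskal-Wallis", kw$statistic, kw$p.value),
      comparisons = cmp[, c("group", "statistic", "p_unadjusted",
                            "p_adjusted")],
      rank = TRUE), class = "anova_dunnett"))
  }
  av <- stats::anova(stats::lm(y ~ f))
  n <- lengths(g)
  k <- length(g)
  df <- sum(n) - k
  s2 <- av[["Mean Sq"]][2L]
  means <- vapply(g, mean, 0)
  tstat <- (means[-1L] - means[1L]) / sqrt(s2 * (1 / n[-1L] + 1 / n[1L]))
  if (is.null(reference))
    reference <- dunnett_reference(n, ndraws = ndraws, seed = seed)
  p_adj <- vapply(tstat, function(t)
    (sum(reference >= abs(t)) + 1) / (length(reference) + 1), 0)
  p_un <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(
    anova = .test_result("one-way ANOVA F",
                         av[["F value"]][1L], av[["Pr(>F)"]][1L]),
    comparisons = data.frame(group = labs[-1L], statistic = tstat,
                             p_unadjusted = p_un, p_adjusted = pmin(1, p_adj)),
    rank = FALSE), class = "anova_dunnett")
}

## Dunn's z statistics vs the first (control) level, Bonferroni-adjusted,
## with tie correction
.dunn_vs_control <- function(y, f) {
  N <- length(y)
  rk <- rank(y)
  tie <- table(y)
  tiecor <- 1 - sum(tie^3 - tie) / (N^3 - N)
  rbar <- tapply(rk, f, mean)
  n <- tabulate(f)
  m <- nlevels(f) - 1L
  z <- (rbar[-1L] - rbar[1L]) /
    sqrt(N * (N + 1) / 12 * tiecor * (1 / n[-1L] + 1 / n[1L]))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(statistic = as.numeric(z), p_unadjusted = p,
             p_adjusted = pmin(1, p * m))
}

#' @export
print.anova_dunnett <- function(x, ...) {
  print(x$anova)
  df <- x$comparisons
  for (i in seq_len(nrow(df)))
    cat(sprintf("  vs control, group %s: stat %.3g, adj p = %.4g\n",
                df$group[i], df$statistic[i], df$p_adjusted[i]))
  invisible(x)
}

#' Size-cutoff sensitivity analysis of normalized viable areas
#'
#' Tests whether the quantified (normalized) live tumor area depends on
#' the minimum nodule size cut-off. The cut-off is a within-replicate
#' factor (the same wells are re-quantified at every cut-off), so each
#' treatment group is analysed with a repeated-measures one-way ANOVA
#' across cut-offs; the analysis is "threshold-stable" when no group shows
#' a cut-off effect at the 0.05 level, mirroring the reference finding of
#' no significant difference over 500--3000 um^2.
#'
#' @param tbl Data frame with columns `group`, `replicate`, `cutoff`,
#'   `area` (or `normalized_area`); every replicate must appear at every
#'   cut-off within its group.
#' @param alpha Significance level for the stability flag.
#' @return A list of class `"threshold_sensitivity"`: `per_group`
#'   (data frame of F and p per group) and `stable` (logical).
#' @export
threshold_sensitivity <- function(tbl, alpha = 0.05) {
  stopifnot(is.data.frame(tbl))
  if (!"area" %in% names(tbl) && "normalized_area" %in% names(tbl))
    tbl$area <- tbl$normalized_area
  need <- c("group", "replicate", "cutoff", "area")
  if (!all(need %in% names(tbl)))
    stop("tbl must have columns group, replicate, cutoff, area", call. = FALSE)
  res <- lapply(split(tbl, tbl$group), function(d) {
    wide <- table(d$replicate, d$cutoff)
    if (any(wide != 1L))
      stop("every replicate must appear exactly once at every cutoff",
           call. = FALSE)
    .rm_anova(d$area, factor(d$cutoff), factor(d$replicate))
  })
  per_group <- data.frame(group = names(res),
                          F = vapply(res, `[[`, 0, "F"),
                          p = vapply(res, `[[`, 0, "p"),
                          row.names = NULL)
  structure(list(per_group = per_group,
                 stable = all(per_group$p > alpha), alpha = alpha),
            class = "threshold_sensitivity")
}

## one-way repeated-measures ANOVA (subject-blocked) by direct sums of
## squares; degenerate zero-variance cases give p = 1
.rm_anova <- function(y, fac, subj) {
  K <- nlevels(fac); n <- nlevels(subj)
  gm <- mean(y)
  ss_tot <- sum((y - gm)^2)
  ss_a <- n * sum((tapply(y, fac, mean) - gm)^2)
  ss_s <- K * sum((tapply(y, subj, mean) - gm)^2)
  ss_e <- max(0, ss_tot - ss_a - ss_s)
  if (ss_a <= 1e-12 * max(ss_tot, 1e-300) || K < 2L || n < 2L)
    return(list(F = 0, p = 1))
  if (ss_e <= 1e-12 * max(ss_tot, 1e-300))
    return(list(F = Inf, p = 0))
  F <- (ss_a / (K - 1)) / (ss_e / ((K - 1) * (n - 1)))
  list(F = F, p = stats::pf(F, K - 1, (K - 1) * (n - 1), lower.tail = FALSE))
}

#' @export
print.threshold_sensitivity <- function(x, ...) {
  cat(sprintf("Threshold sensitivity (alpha = %g): %s\n", x$alpha,
              if (x$stable) "threshold-stable (all p > alpha)"
              else "NOT threshold-stable"))
  print(x$per_group)
  invisible(x)
}
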