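#' Assign proteins to the ANOVA grouping schemes
#'
#' Multi-pathway proteins (e.g. "T,P") are assigned by their first-listed
#' pathway code, the only ordering the source tables provide. Two schemes
#' are defined: `six_group` keeps glycolysis (G), TCA cycle (T), metabolite
#' transport (M), respiratory chain (R) and glutathione (S) separate and
#' merges the pyruvate cycle and NADH shuttle (P, N) into `PN`;
#' `five_group_figure3` merges T, P and N into `TPN` (the boxplot grouping).
#'
#' @param x a [StudyFixture-class] or records data.frame.
#' @param scheme `"six_group"` (default) or `"five_group_figure3"`.
#' @return named character vector: protein abbreviation -> group label.
#' @examples
#' g <- assignAnovaGroups(loadFixture("gsis69"))
#' table(g)
#' @export
assignAnovaGroups <- function(x, scheme = c("six_group",
                                            "five_group_figure3")) {
  scheme <- match.arg(scheme)
  r <- asRecords(x)
  first <- primaryPathway(r)
  if (any(!nzchar(first)))
    stop("record(s) with empty pathway list: ",
         paste(r$abbrev[!nzchar(first)], collapse = ", "))
  grp <- switch(scheme,
    six_group = ifelse(first %in% c("P", "N"), "PN", first),
    five_group_figure3 = ifelse(first %in% c("T", "P", "N"), "TPN", first))
  stats::setNames(grp, r$abbrev)
}

## Common entry: accept a grouping vector or a scheme name.
resolveGrouping <- function(x, grouping) {
  if (is.character(grouping) && length(grouping) == 1L &&
      is.null(names(grouping)))
    grouping <- assignAnovaGroups(x, grouping)
  grouping
}

#' One-way divergence ANOVA
#'
#' Fixed-effects one-way analysis of variance of human-mouse percent
#' similarity across groups (pathway grouping by default). Errors when only
#' one group is present or when both the between- and within-group variances
#' are zero (F undefined).
#'
#' @param x a [StudyFixture-class] or records data.frame.
#' @param grouping named protein -> group vector, or a scheme name for
#'   [assignAnovaGroups()] (default `"six_group"`).
#' @return list with `f_statistic`, `df_between`, `df_within`, `p`,
#'   `group_means`, and the underlying `aov` fit.
#' @examples
#' divergenceAnova(loadFixture("gsis69"))[c("f_statistic", "p")]
#' @export
divergenceAnova <- function(x, grouping = "six_group") {
  r <- asRecords(x)
  grouping <- resolveGrouping(x, grouping)
  r <- r[r$abbrev %in% names(grouping), , drop = FALSE]
  g <- factor(grouping[r$abbrev])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  v <- r$hm_similarity
  withinVar <- tapply(v, g, function(x)
    if (length(x) < 2L) NA_real_ else stats::var(x))
  if (all(is.na(withinVar) | withinVar == 0)) {
    if (stats::var(v) == 0)
      stop("F undefined: zero variance within and between groups")
    stop("F undefined: zero within-group variance")
  }
  fit <- stats::aov(v ~ g)
  tab <- summary(fit)[[1]]
  list(f_statistic = tab$`F value`[1],
       df_between = tab$Df[1], df_within = tab$Df[2],
       p = tab$`Pr(>F)`[1],
       group_means = tapply(v, g, mean),
       fit = fit)
}

#' Tukey HSD pairwise group comparisons
#'
#' All pairwise group mean differences with studentized-range adjusted
#' p-values, following the divergence ANOVA.
#'
#' @inheritParams divergenceAnova
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame with `group_a`, `group_b`, `diff` (mean a - mean b),
#'   `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukeyHsd <- function(x, grouping = "six_group", alpha = 0.05) {
  an <- divergenceAnova(x, grouping)
  tk <- stats::TukeyHSD(an$fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group_a = vapply(pairs, `[`, "", 1L),
    group_b = vapply(pairs, `[`, "", 2L),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"])
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Spearman's rho with midrank ties; two-tailed p by exact enumeration for
#' n <= 9 without ties, otherwise by the t approximation.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return list with `rho`, `p_two_tailed`, `n`.
#' @export
spearmanCorrelation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector: rho undefined")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= 9L && !ties)))
  list(rho = unname(ct$estimate), p_two_tailed = ct$p.value, n = n)
}

#' Disease-gene comparisons
#'
#' Three comparisons of the disease-associated proteins (those with at least
#' one OMIM entry) against the rest of the cohort: (i) a two-sample t-test
#' on human-mouse similarity (Welch by default; `varEqual = TRUE` for the
#' pooled-variance variant); (ii) a chi-squared goodness-of-fit of the
#' Universal proportion among disease genes against the cohort-wide
#' proportion; (iii) a 2x2 chi-squared (1 df, no continuity correction by
#' default) of positive-selection history against disease membership, a gene
#' counting as selected if it has at least one recorded episode.
#'
#' @param x a [StudyFixture-class] or records data.frame with `disease` and
#'   `selection` list-columns.
#' @param varEqual pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @param yates apply Yates continuity correction to the 2x2 test
#'   (default `FALSE`).
#' @return list with `n_disease`, `mean_disease`, `mean_other`, `t_p`,
#'   `n_disease_universal`, `class_chi2`, `class_chi2_p`, `possel_table`,
#'   `possel_chi2`, `possel_chi2_p`.
#' @examples
#' str(diseaseComparisons(loadFixture("gsis69")))
#' @export
diseaseComparisons <- function(x, varEqual = FALSE, yates = FALSE) {
  r <- asRecords(x)
  isDis <- hasDisease(r)
  isSel <- hasSelection(r)
  if (sum(isDis) < 2L || sum(!isDis) < 2L)
    stop("need at least 2 proteins in each arm")
  v <- r$hm_similarity
  tt <- stats::t.test(v[isDis], v[!isDis], var.equal = varEqual)
  isU <- r$phylo_class == "U"
  obs <- c(U = sum(isU & isDis), other = sum(!isU & isDis))
  ref <- c(U = sum(isU), other = sum(!isU)) / length(isU)
  gof <- compareComposition(obs, ref)
  tab <- table(selected = factor(isSel, levels = c(TRUE, FALSE)),
               disease = factor(isDis, levels = c(TRUE, FALSE)))
  cs <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(n_disease = sum(isDis),
       mean_disease = mean(v[isDis]), mean_other = mean(v[!isDis]),
       t_p = tt$p.value,
       n_disease_universal = unname(obs["U"]),
       class_chi2 = gof$chi2, class_chi2_p = gof$p,
       possel_table = tab,
       possel_chi2 = unname(cs$statistic), possel_chi2_p = cs$p.value)
}
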