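#' Summary statistics of human-mouse conservation
#'
#' Arithmetic mean, sample (n-1) standard deviation, minimum, maximum and
#' the count of proteins strictly above a stated similarity threshold.
#'
#' @param x a [StudyFixture-class], records data.frame, or numeric vector of
#'   percent similarities.
#' @param threshold percent; `n_above_threshold` counts values strictly
#'   above it (default 99, the "very highly conserved" cut).
#' @return list with `n`, `mean`, `sd`, `min`, `max`, `n_above_threshold`,
#'   `threshold`.
#' @examples
#' conservationSummary(loadFixture("gsis69"))
#' @export
conservationSummary <- function(x, threshold = 99) {
  v <- if (is.numeric(x)) x else asRecords(x)$hm_similarity
  if (length(v) < 2L) stop("need at least 2 values for a summary (sd)")
  list(n = length(v), mean = mean(v), sd = stats::sd(v),
       min = min(v), max = max(v),
       n_above_threshold = sum(v > threshold), threshold = threshold)
}

#' Quintile bins of the similarity distribution
#'
#' Assigns each protein to one of five bins spanning the empirical quintile
#' intervals of the similarity distribution (bin 1 = least conserved, bin 5 =
#' most conserved). Ties are assigned to the lower bin, so identical values
#' always share a bin; otherwise bin sizes differ by at most one.
#'
#' @param x a [StudyFixture-class], records data.frame, or named numeric
#'   vector of similarities.
#' @return named integer vector of bins in 1..5.
#' @export
quintileBins <- function(x) {
  if (is.numeric(x)) {
    v <- x
    nm <- names(x)
  } else {
    r <- asRecords(x)
    v <- r$hm_similarity
    nm <- r$abbrev
  }
  n <- length(v)
  if (n < 5L) stop("need at least 5 values for quintile binning")
  ## minimum rank of each tied block puts the whole block in the lower bin
  rk <- rank(v, ties.method = "min")
  bins <- as.integer(floor((rk - 1) * 5 / n) + 1L)
  stats::setNames(bins, nm)
}

#' Tukey-fence outliers within pathway groups
#'
#' Flags proteins whose similarity lies below Q1 - 1.5 IQR or above
#' Q3 + 1.5 IQR within their group, with quartiles by linear interpolation
#' ([stats::quantile()] type 7) — the operational definition behind a
#' Tukey boxplot's outlier points. Groups with fewer than 4 members yield no
#' outliers (with a warning): fences from so few points are not meaningful.
#'
#' The proteins this flags on the study cohort under the five-group scheme —
#' rapidly evolving relative to their own sub-pathway — are the candidate
#' "adapter" proteins sitting at sub-pathway interfaces.
#'
#' @param x a [StudyFixture-class] or records data.frame.
#' @param grouping named character vector mapping protein abbreviation to
#'   group (see [assignAnovaGroups()]).
#' @return data.frame with columns `protein`, `group`, `similarity`, `side`
#'   (`"low"`/`"high"`), plus the per-group fences as attributes.
#' @examples
#' fx <- loadFixture("gsis69")
#' pathwayOutliers(fx, assignAnovaGroups(fx, "five_group_figure3"))
#' @export
pathwayOutliers <- function(x, grouping) {
  r <- asRecords(x)
  if (length(grouping) == 0L) stop("empty grouping")
  stopifnot(!is.null(names(grouping)))
  r <- r[r$abbrev %in% names(grouping), , drop = FALSE]
  grp <- grouping[r$abbrev]
  out <- list()
  fences <- list()
  for (g in sort(unique(grp))) {
    i <- which(grp == g)
    if (length(i) < 4L) {
      warning("group '", g, "' has fewer than 4 members; no outlier call")
      next
    }
    v <- r$hm_similarity[i]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    fences[[g]] <- c(lower = lo, upper = hi)
    low <- i[v < lo]
    high <- i[v > hi]
    if (length(low))
      out[[length(out) + 1L]] <- data.frame(
        protein = r$abbrev[low], group = g,
        similarity = r$hm_similarity[low], side = "low")
    if (length(high))
      out[[length(out) + 1L]] <- data.frame(
        protein = r$abbrev[high], group = g,
        similarity = r$hm_similarity[high], side = "high")
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(protein = character(0), group = character(0),
                         similarity = numeric(0), side = character(0))
  rownames(res) <- NULL
  attr(res, "fences") <- fences
  res
}
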