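#' Phylogenetic-age classification of a hit profile
#'
#' Non-hierarchical rule applied in fixed order: Universal (U) if the protein
#' hits more than five prokaryote genomes; else Eukaryote-specific (E) if it
#' hits at least one non-metazoan eukaryote; else Metazoan-specific (M) if it
#' hits at least one non-mammalian metazoan; else Vertebrate-specific (V).
#' Exactly five prokaryote hits do not qualify as Universal. Counts are
#' distinct genomes, not individual HSPs.
#'
#' @param profile a [HitProfile-class] or a named count vector over
#'   `prokaryote`, `nonmetazoan_eukaryote`, `nonmammalian_metazoan`
#'   (and optionally `vertebrate`).
#' @return one of `"U"`, `"E"`, `"M"`, `"V"`.
#' @examples
#' classifyProfile(c(prokaryote = 6, nonmetazoan_eukaryote = 0,
#'                   nonmammalian_metazoan = 0, vertebrate = 2))
#' @export
classifyProfile <- function(profile) {
  h <- if (is(profile, "HitProfile")) hitCounts(profile) else profile
  stopifnot(all(c("prokaryote", "nonmetazoan_eukaryote",
                  "nonmammalian_metazoan") %in% names(h)))
  if (h[["prokaryote"]] > 5) return("U")
  if (h[["nonmetazoan_eukaryote"]] >= 1) return("E")
  if (h[["nonmammalian_metazoan"]] >= 1) return("M")
  "V"
}

#' Class composition of a protein cohort
#'
#' Integer counts and rounded integer percentages of the four phylogenetic
#' age classes.
#'
#' @param x a [StudyFixture-class] or records data.frame (may be empty).
#' @return data.frame with columns `class`, `count`, `percent`.
#' @examples
#' classComposition(loadFixture("gsis69"))
#' @export
classComposition <- function(x) {
  r <- asRecords(x)
  cls <- factor(r$phylo_class, levels = names(PHYLO_CLASSES))
  counts <- tabulate(cls, nbins = 4L)
  pct <- if (sum(counts) == 0L) rep(0L, 4L)
         else as.integer(round(100 * counts / sum(counts)))
  data.frame(class = names(PHYLO_CLASSES), count = counts, percent = pct)
}

#' Goodness-of-fit test of class composition against reference proportions
#'
#' Pearson chi-squared goodness-of-fit of observed class counts against
#' expected counts `total x reference`, with df = k - 1 and an upper-tail
#' p-value. Reference proportions are normalized, so any positive scaling of
#' them gives the same statistic.
#'
#' @param observed named or unnamed integer counts.
#' @param reference positive reference proportions, same length.
#' @return list with `observed`, `expected`, `chi2`, `df`, `p`.
#' @examples
#' fx <- loadFixture("gsis69")
#' compareComposition(classComposition(fx)$count, referenceProportions(fx))
#' @export
compareComposition <- function(observed, reference) {
  stopifnot(length(observed) == length(reference), all(reference >= 0))
  total <- sum(observed)
  if (total <= 0) stop("observed total must be positive")
  p <- reference / sum(reference)
  expected <- total * p
  if (any(expected == 0 & observed > 0))
    stop("expected cell is zero where observed count is nonzero")
  keep <- expected > 0
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- length(observed) - 1L
  list(observed = observed, expected = expected, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Shared-homologue clusters
#'
#' Proteins sharing homologues in other genomes indicate a history of
#' ancient gene duplication. Builds a weighted graph whose edge weights are
#' the sizes of pairwise homologue-set intersections, keeps edges with
#' weight >= `minShared`, and reports the connected components
#' (single linkage), each with its maximal pairwise shared count.
#'
#' @param profiles list of [HitProfile-class] with `homologIds` populated.
#' @param minShared minimum shared-homologue count for an edge (default 1).
#' @return list of clusters, each `list(proteins =, max_shared =)`;
#'   singletons have `max_shared = 0`. Ordered by decreasing size, then
#'   protein name.
#' @export
sharedHomologClusters <- function(profiles, minShared = 1L) {
  if (minShared < 1L) stop("minShared must be >= 1")
  prots <- vapply(profiles, function(p) p@protein, "")
  ids <- lapply(profiles, homologIds)
  n <- length(profiles)
  edges <- integer(0)
  w <- integer(0)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(ids[[i]], ids[[j]]))
    if (shared >= minShared) {
      edges <- c(edges, i, j)
      w <- c(w, shared)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges, weight = w)
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(seq_len(n), comp), function(i) {
    mx <- 0L
    if (length(i) > 1L && length(edges)) {
      em <- matrix(edges, ncol = 2, byrow = TRUE)
      inC <- em[, 1] %in% i & em[, 2] %in% i
      if (any(inC)) mx <- max(w[inC])
    }
    list(proteins = sort(prots[i]), max_shared = mx)
  })
  ord <- order(-vapply(clusters, function(cl) length(cl$proteins), 1L),
               vapply(clusters, function(cl) cl$proteins[1], ""))
  unname(clusters[ord])
}
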