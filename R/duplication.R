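#' Default vertebrate taxon/age bin schedule
#'
#' The taxon labels and approximate ages (MYA) attached to gene-tree nodes,
#' ordered from oldest to youngest. The default ships the eight taxa the
#' study names with explicit dates: Euteleostomi 420, Tetrapoda 359,
#' Clupeocephala 320, Percomorpha 190, Theria 166, Eutheria 102, Murinae 37,
#' Catarrhini 31. The oldest bin is the vertebrate root: duplications at
#' older (non-vertebrate) taxa fall outside the schedule window and are
#' excluded by construction.
#'
#' @return data.frame with columns `taxon` and `age`.
#' @export
defaultTaxonSchedule <- function() {
  data.frame(
    taxon = c("Euteleostomi", "Tetrapoda", "Clupeocephala", "Percomorpha",
              "Theria", "Eutheria", "Murinae", "Catarrhini"),
    age = c(420, 359, 320, 190, 166, 102, 37, 31),
    stringsAsFactors = FALSE)
}

## taxa treated silently as pre-vertebrate when met on the focal lineage
OLDER_TAXA <- c("Opisthokonta", "Bilateria", "Coelomata", "Chordata",
                "Eukaryota", "Metazoa", "Fungi/Metazoa group")

#' Extract a duplication-history vector from an annotated gene tree
#'
#' Walks the ancestral path from the root to the focal leaf and counts
#' duplication-flagged nodes per schedule bin (matched by taxon label).
#' Nodes at or above a family-founding duplication (`F=Y`) are excluded: the
#' vector only reflects history within the focal gene's own family. Taxa in
#' `olderTaxa` (or any taxon, once above the founder) are outside the
#' vertebrate window and contribute nothing. Other unmappable taxa are an
#' error in strict mode, or dropped with a warning otherwise.
#'
#' @param tree a [GeneTree-class].
#' @param focal focal leaf label.
#' @param schedule taxon/age bin schedule (default [defaultTaxonSchedule()]).
#' @param strict error on duplication nodes with unmappable taxa
#'   (default `TRUE`).
#' @param olderTaxa taxon labels treated as pre-vertebrate.
#' @return a one-gene [DuplicationHistory-class].
#' @export
extractDuplicationVector <- function(tree, focal,
                                     schedule = defaultTaxonSchedule(),
                                     strict = TRUE, olderTaxa = OLDER_TAXA) {
  stopifnot(is(tree, "GeneTree"))
  phy <- tree@tree
  tipIdx <- match(focal, phy$tip.label)
  if (is.na(tipIdx)) stop("focal leaf '", focal, "' not in tree")
  root <- length(phy$tip.label) + 1L
  path <- ape::nodepath(phy, from = root, to = tipIdx)
  path <- path[-length(path)]  # ancestral internal nodes, root -> parent
  nd <- tree@nodeData[path, , drop = FALSE]
  ## truncate at the most recent family-founding duplication: nodes at or
  ## above the founder belong to older families
  if (any(nd$familyFounder)) {
    cut <- max(which(nd$familyFounder))
    nd <- nd[seq_len(nrow(nd)) > cut, , drop = FALSE]
  }
  nd <- nd[nd$isDuplication, , drop = FALSE]
  counts <- stats::setNames(integer(nrow(schedule)), schedule$taxon)
  for (i in seq_len(nrow(nd))) {
    tx <- nd$taxon[i]
    bin <- match(tx, schedule$taxon)
    if (is.na(bin)) {
      if (!is.na(tx) && tx %in% olderTaxa) next
      msg <- paste0("duplication node with unmappable taxon: ",
                    if (is.na(tx)) "<none>" else tx)
      if (strict) stop(msg)
      warning(msg, "; dropped")
      next
    }
    counts[bin] <- counts[bin] + 1L
  }
  new("DuplicationHistory",
      counts = matrix(counts, nrow = 1,
                      dimnames = list(focal, schedule$taxon)),
      schedule = schedule)
}

#' Combine per-gene duplication histories sharing one schedule
#'
#' @param histories list of [DuplicationHistory-class] on identical
#'   schedules.
#' @return a single [DuplicationHistory-class] with one row per gene.
#' @export
combineHistories <- function(histories) {
  stopifnot(length(histories) >= 1L,
            all(vapply(histories, is, TRUE, "DuplicationHistory")))
  s1 <- taxonSchedule(histories[[1]])
  same <- vapply(histories, function(h) identical(taxonSchedule(h), s1), TRUE)
  if (!all(same)) stop("histories use mixed bin schedules")
  new("DuplicationHistory",
      counts = do.call(rbind, lapply(histories, dupCounts)), schedule = s1)
}

#' Euclidean distance matrix between duplication vectors
#'
#' d(i, j) = sqrt(sum over bins of (c_i - c_j)^2); zero diagonal, symmetric.
#'
#' @param x a [DuplicationHistory-class] (or genes-by-bins matrix).
#' @return full symmetric numeric matrix with gene dimnames.
#' @export
euclideanDistanceMatrix <- function(x) {
  m <- if (is(x, "DuplicationHistory")) dupCounts(x) else as.matrix(x)
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Hierarchical clustering of duplication histories
#'
#' Agglomerative clustering of the distance matrix (complete linkage by
#' default, the base-R `hclust` default family) plus the flat clusters at
#' merge height 0 — the groups of genes with exactly identical duplication
#' histories, which are the interpretable units of shared history.
#'
#' @param distmat symmetric distance matrix with zero diagonal.
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return list with `hclust` (the dendrogram) and `clusters`
#'   (named integer vector of zero-height cluster ids).
#' @export
hierarchicalCluster <- function(distmat, linkage = "complete") {
  distmat <- as.matrix(distmat)
  if (nrow(distmat) != ncol(distmat) ||
      !isTRUE(all.equal(distmat, t(distmat), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  hc <- stats::hclust(stats::as.dist(distmat), method = linkage)
  list(hclust = hc, clusters = stats::cutree(hc, h = 0))
}

#' Mann-Whitney test of within-group vs background distances
#'
#' Compares the pairwise distances among members of one group against all
#' remaining pairwise distances (two-sided rank-sum test; exact enumeration
#' where `wilcox.test` supports it, normal approximation with tie
#' correction otherwise). A significantly smaller within-group median means
#' the group's duplication histories are clustered; significantly larger
#' means anticlustered. The Bonferroni-adjusted p multiplies the raw p by
#' the number of groups tested in the same family of tests.
#'
#' Because the pairwise distances entering the test share genes, the plain
#' rank-sum p-value is anticonservative under a random-membership null; for
#' a calibrated alternative, `nPermutations > 0` additionally computes a
#' label-permutation p-value by re-drawing random groups of the same size
#' and comparing the within-group rank sum against its permutation
#' distribution.
#'
#' @param distmat symmetric distance matrix with gene dimnames.
#' @param membership named character vector mapping gene to group.
#' @param group group label to test (>= 2 members).
#' @param nGroupsTested Bonferroni multiplicity (default 1).
#' @param alpha significance level used to call the direction
#'   (default 0.05, on the raw p).
#' @param nPermutations label permutations for the calibrated p-value
#'   (default 0 = not computed).
#' @return a [GroupTestResult-class].
#' @export
groupClusteringTest <- function(distmat, membership, group,
                                nGroupsTested = 1L, alpha = 0.05,
                                nPermutations = 0L) {
  distmat <- as.matrix(distmat)
  genes <- rownames(distmat)
  stopifnot(!is.null(genes), !is.null(names(membership)))
  membership <- membership[intersect(names(membership), genes)]
  members <- names(membership)[membership == group]
  if (length(members) < 2L)
    stop("group '", group, "' has fewer than 2 members")
  idx <- match(members, genes)
  allPairs <- pairIndices(seq_along(genes))
  within <- allPairs[, 1] %in% idx & allPairs[, 2] %in% idx
  if (!any(!within)) stop("no background pairs")
  dWithin <- distmat[allPairs[within, , drop = FALSE]]
  dBack <- distmat[allPairs[!within, , drop = FALSE]]
  wt <- suppressWarnings(
    stats::wilcox.test(dWithin, dBack, alternative = "two.sided"))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied distances carry no evidence
  dir <- "none"
  if (is.finite(p) && p < alpha) {
    dir <- if (stats::median(dWithin) < stats::median(dBack)) "clustered"
           else if (stats::median(dWithin) > stats::median(dBack))
             "anticlustered"
           else "none"
  }
  pPerm <- NA_real_
  if (nPermutations > 0L) {
    nw <- length(dWithin)
    rankSum <- function(ii) {
      w <- allPairs[, 1] %in% ii & allPairs[, 2] %in% ii
      sum(rank(distmat[rbind(allPairs[w, , drop = FALSE],
                             allPairs[!w, , drop = FALSE])])[seq_len(nw)])
    }
    obs <- rankSum(idx)
    mu <- nw * (nrow(allPairs) + 1) / 2  # exact null mean of the rank sum
    nullDev <- replicate(nPermutations, abs(
      rankSum(sample(seq_along(genes), length(idx))) - mu))
    pPerm <- (1 + sum(nullDev >= abs(obs - mu))) / (nPermutations + 1)
  }
  new("GroupTestResult", group = group,
      nWithinPairs = length(dWithin), nBackgroundPairs = length(dBack),
      uStatistic = unname(wt$statistic), pRaw = p,
      pBonferroni = min(1, p * nGroupsTested), pPermutation = pPerm,
      direction = dir)
}

#' Leave-one-gene-out re-test of group clustering
#'
#' Removes one gene's row/column from the distance matrix (and from the
#' membership) and re-runs [groupClusteringTest()] — used to check whether a
#' group's (anti)clustering signal is driven by a single gene. Removing a
#' gene that is not in the tested group leaves the result unchanged (with a
#' warning).
#'
#' @inheritParams groupClusteringTest
#' @param gene gene to exclude; the group must keep >= 2 members.
#' @return a [GroupTestResult-class].
#' @export
excludeGeneAndRetest <- function(distmat, membership, group, gene,
                                 nGroupsTested = 1L, alpha = 0.05) {
  distmat <- as.matrix(distmat)
  members <- names(membership)[membership == group]
  if (!gene %in% members) {
    warning("gene '", gene, "' is not in group '", group,
            "'; result unchanged")
    return(groupClusteringTest(distmat, membership, group, nGroupsTested,
                               alpha))
  }
  if (length(members) < 3L)
    stop("excluding '", gene, "' would leave group '", group,
         "' with fewer than 2 members")
  keep <- setdiff(rownames(distmat), gene)
  groupClusteringTest(distmat[keep, keep, drop = FALSE],
                      membership[setdiff(names(membership), gene)],
                      group, nGroupsTested, alpha)
}
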