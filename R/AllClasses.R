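#' @import methods
NULL

## Closed vocabularies of the study design. Pathway codes follow the network's
## sub-pathway labelling; phylogenetic classes are gene-age categories assigned
## from the taxonomic breadth of detectable homology.
PATHWAY_CODES <- c(
  G = "glycolysis", T = "TCA cycle", P = "pyruvate cycle",
  N = "NADH shuttle", R = "respiratory chain", M = "metabolite transport",
  S = "glutathione pathway"
)

PHYLO_CLASSES <- c(U = "Universal", E = "Eukaryote-specific",
                   M = "Metazoan-specific", V = "Vertebrate-specific")

HIT_CATEGORIES <- c("prokaryote", "nonmetazoan_eukaryote",
                    "nonmammalian_metazoan", "vertebrate", "mammal")

## Profile categories after collapsing mammal-only hits into vertebrate
PROFILE_CATEGORIES <- HIT_CATEGORIES[1:4]

#' StudyFixture: a cohort of network proteins plus genome-wide reference
#' class proportions
#'
#' Container for a set of protein records (one row per network protein:
#' sub-pathway codes, phylogenetic class, human-mouse percent similarity,
#' duplication counts, positive-selection episodes, OMIM disease
#' associations) together with the reference proportions of the four
#' phylogenetic age classes in the whole metabolic complement of the human
#' genome, against which the cohort's composition is tested.
#'
#' @slot records data.frame with columns `abbrev`, `protein_name`,
#'   `swissprot_id`, `pathways` (comma-separated ordered codes), `phylo_class`,
#'   `hm_similarity`, `n_duplications`, and list-columns `selection`
#'   (per-protein data.frame of taxon/age episodes) and `disease`
#'   (per-protein data.frame of OMIM code/disease name).
#' @slot referenceProportions named numeric of length 4 (U, E, M, V) summing
#'   to 1.
#' @slot info free-form fixture metadata (provenance notes, exclusions).
#' @export
setClass("StudyFixture",
  representation(records = "data.frame",
                 referenceProportions = "numeric",
                 info = "list"))

setValidity("StudyFixture", function(object) {
  msg <- character(0)
  r <- object@records
  needed <- c("abbrev", "swissprot_id", "pathways", "phylo_class",
              "hm_similarity")
  if (!all(needed %in% names(r)))
    msg <- c(msg, paste("records must have columns:",
                        paste(needed, collapse = ", ")))
  else {
    if (anyDuplicated(r$abbrev))
      msg <- c(msg, "duplicated protein abbreviations")
    if (any(!is.finite(r$hm_similarity) | r$hm_similarity < 0 |
            r$hm_similarity > 100))
      msg <- c(msg, "hm_similarity must lie in [0, 100]")
    codes <- unlist(strsplit(r$pathways, ","))
    codes <- trimws(codes)
    if (any(!nzchar(r$pathways)))
      msg <- c(msg, "every record needs at least one pathway code")
    if (length(codes) && !all(codes %in% names(PATHWAY_CODES)))
      msg <- c(msg, paste("unknown pathway code(s):",
                          paste(setdiff(codes, names(PATHWAY_CODES)),
                                collapse = ", ")))
    if (!all(r$phylo_class %in% names(PHYLO_CLASSES)))
      msg <- c(msg, "phylo_class must be one of U, E, M, V")
    if ("disease" %in% names(r)) {
      omim <- unlist(lapply(r$disease, function(d) d$omim_code))
      if (length(omim) && !all(grepl("^[0-9]{6}$", omim)))
        msg <- c(msg, "OMIM codes must be 6-digit strings")
    }
  }
  p <- object@referenceProportions
  if (length(p) != 4L || !setequal(names(p), names(PHYLO_CLASSES)))
    msg <- c(msg, "referenceProportions must be named U, E, M, V")
  else if (abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "referenceProportions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' AlignmentResult: a scored global pairwise protein alignment
#'
#' @slot alignedA,alignedB gapped aligned sequences of equal length.
#' @slot score substitution-matrix sum minus affine gap penalties
#'   (a gap of length L costs `gapOpening + L * gapExtension`).
#' @slot percentIdentity,percentSimilarity percentages over all alignment
#'   columns (gap columns count in the denominator only).
#' @slot gapColumns number of columns containing a gap in either sequence.
#' @export
setClass("AlignmentResult",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", percentIdentity = "numeric",
                 percentSimilarity = "numeric", gapColumns = "integer"))

setValidity("AlignmentResult", function(object) {
  msg <- character(0)
  if (nchar(object@alignedA) != nchar(object@alignedB))
    msg <- c(msg, "aligned sequences must have equal length")
  for (p in c(object@percentIdentity, object@percentSimilarity))
    if (!is.finite(p) || p < -1e-9 || p > 100 + 1e-9)
      msg <- c(msg, "percentages must lie in [0, 100]")
  if (object@percentIdentity > object@percentSimilarity + 1e-9)
    msg <- c(msg, "percent identity cannot exceed percent similarity")
  if (length(msg)) msg else TRUE
})

#' HitProfile: per-protein homology-hit counts by taxonomic category
#'
#' Counts of distinct genomes with at least one retained homology hit, in the
#' four categories used for phylogenetic-age classification (mammal-only hits
#' are collapsed into the vertebrate category when a profile is built from a
#' hit table).
#'
#' @slot protein query protein identifier.
#' @slot hits named non-negative integer vector over
#'   `prokaryote`, `nonmetazoan_eukaryote`, `nonmammalian_metazoan`,
#'   `vertebrate`.
#' @slot homologIds identifiers of the subject sequences (or genomes, when no
#'   subject column is available) hit by the query; used for shared-homologue
#'   cluster detection.
#' @export
setClass("HitProfile",
  representation(protein = "character", hits = "integer",
                 homologIds = "character"))

setValidity("HitProfile", function(object) {
  msg <- character(0)
  if (!setequal(names(object@hits), PROFILE_CATEGORIES))
    msg <- c(msg, paste("hits must be named:",
                        paste(PROFILE_CATEGORIES, collapse = ", ")))
  if (any(object@hits < 0)) msg <- c(msg, "hit counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GeneTree: a rooted gene tree with duplication annotations
#'
#' Wraps an `ape` phylo object read from Newick/NHX together with per-node
#' annotation: whether the node is a duplication (NHX `D=Y`), the taxon label
#' of the node (`T=`), its age in MYA (`A=`), and whether it founded a new
#' gene family (`F=Y`, truncating duplication-history extraction).
#'
#' @slot tree an [ape::read.tree()]-style `phylo` object.
#' @slot nodeData data.frame with one row per node (tips then internals, in
#'   `phylo` node numbering): `node`, `isDuplication`, `taxon`, `age`,
#'   `familyFounder`.
#' @export
setClass("GeneTree",
  representation(tree = "ANY", nodeData = "data.frame"))

setValidity("GeneTree", function(object) {
  msg <- character(0)
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  needed <- c("node", "isDuplication", "taxon", "age", "familyFounder")
  if (!all(needed %in% names(object@nodeData)))
    msg <- c(msg, paste("nodeData needs columns:",
                        paste(needed, collapse = ", ")))
  else if (inherits(object@tree, "phylo")) {
    n <- length(object@tree$tip.label) + object@tree$Nnode
    if (nrow(object@nodeData) != n)
      msg <- c(msg, "nodeData must have one row per node")
  }
  if (length(msg)) msg else TRUE
})

#' DuplicationHistory: binned ancestral duplication counts per gene
#'
#' A genes-by-bins matrix of duplication counts on each focal gene's
#' root-to-leaf lineage, indexed by a taxon/age bin schedule ordered from
#' oldest to youngest.
#'
#' @slot counts integer matrix, rows = genes, columns = schedule bins.
#' @slot schedule data.frame with columns `taxon` and `age` (MYA), strictly
#'   decreasing in age.
#' @export
setClass("DuplicationHistory",
  representation(counts = "matrix", schedule = "data.frame"))

setValidity("DuplicationHistory", function(object) {
  msg <- character(0)
  s <- object@schedule
  if (!all(c("taxon", "age") %in% names(s)))
    msg <- c(msg, "schedule needs columns taxon, age")
  else {
    if (nrow(s) > 1 && any(diff(s$age) >= 0))
      msg <- c(msg, "schedule ages must strictly decrease (oldest first)")
    if (ncol(object@counts) != nrow(s))
      msg <- c(msg, "counts must have one column per schedule bin")
  }
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GroupTestResult: within-group vs background distance comparison
#'
#' Outcome of the Mann-Whitney comparison of within-group pairwise
#' duplication-history distances against all remaining pairwise distances.
#' `direction` is `clustered` when the within-group median distance is
#' significantly smaller than the background, `anticlustered` when larger,
#' `none` otherwise.
#'
#' @slot group group label tested.
#' @slot nWithinPairs,nBackgroundPairs pair counts entering the test.
#' @slot uStatistic rank-sum statistic (W of [stats::wilcox.test()]).
#' @slot pRaw,pBonferroni two-sided p-value, raw and Bonferroni-adjusted
#'   across the family of groups tested.
#' @slot pPermutation label-permutation p-value of the rank-sum statistic
#'   (`NA` unless permutations were requested); unlike the plain rank-sum
#'   p it remains calibrated although pairwise distances share genes.
#' @slot direction one of `clustered`, `anticlustered`, `none`.
#' @export
setClass("GroupTestResult",
  representation(group = "character", nWithinPairs = "integer",
                 nBackgroundPairs = "integer", uStatistic = "numeric",
                 pRaw = "numeric", pBonferroni = "numeric",
                 pPermutation = "numeric", direction = "character"))

setValidity("GroupTestResult", function(object) {
  msg <- character(0)
  for (p in c(object@pRaw, object@pBonferroni))
    if (!is.finite(p) || p < 0 || p > 1)
      msg <- c(msg, "p-values must lie in [0, 1]")
  if (!object@direction %in% c("clustered", "anticlustered", "none"))
    msg <- c(msg, "direction must be clustered, anticlustered or none")
  if (length(msg)) msg else TRUE
})
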