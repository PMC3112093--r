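#' Accessors for gsisEvol containers
#'
#' `records()` returns the protein table of a [StudyFixture-class];
#' `referenceProportions()` its genome-wide U/E/M/V reference proportions;
#' `fixtureInfo()` its provenance metadata. `alignmentScore()`,
#' `percentIdentity()` and `gapColumns()` read [AlignmentResult-class]
#' slots. `hitCounts()` and `homologIds()` read [HitProfile-class] slots.
#' `dupCounts()` and `taxonSchedule()` read [DuplicationHistory-class]
#' slots.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("referenceProportions",
           function(x) standardGeneric("referenceProportions"))
#' @rdname accessors
#' @export
setGeneric("fixtureInfo", function(x) standardGeneric("fixtureInfo"))
#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setGeneric("percentIdentity", function(x) standardGeneric("percentIdentity"))
#' @rdname accessors
#' @export
setGeneric("gapColumns", function(x) standardGeneric("gapColumns"))
#' @rdname accessors
#' @export
setGeneric("alignedSequences",
           function(x) standardGeneric("alignedSequences"))
#' @rdname accessors
#' @export
setGeneric("hitCounts", function(x) standardGeneric("hitCounts"))
#' @rdname accessors
#' @export
setGeneric("homologIds", function(x) standardGeneric("homologIds"))
#' @rdname accessors
#' @export
setGeneric("dupCounts", function(x) standardGeneric("dupCounts"))
#' @rdname accessors
#' @export
setGeneric("taxonSchedule", function(x) standardGeneric("taxonSchedule"))

#' @rdname accessors
#' @export
setMethod("records", "StudyFixture", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("referenceProportions", "StudyFixture",
          function(x) x@referenceProportions)
#' @rdname accessors
#' @export
setMethod("fixtureInfo", "StudyFixture", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("percentIdentity", "AlignmentResult", function(x) x@percentIdentity)
#' @rdname accessors
#' @export
setMethod("gapColumns", "AlignmentResult", function(x) x@gapColumns)
#' @rdname accessors
#' @export
setMethod("alignedSequences", "AlignmentResult",
          function(x) c(a = x@alignedA, b = x@alignedB))
#' @rdname accessors
#' @export
setMethod("hitCounts", "HitProfile", function(x) x@hits)
#' @rdname accessors
#' @export
setMethod("homologIds", "HitProfile", function(x) x@homologIds)
#' @rdname accessors
#' @export
setMethod("dupCounts", "DuplicationHistory", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("taxonSchedule", "DuplicationHistory", function(x) x@schedule)

setMethod("show", "StudyFixture", function(object) {
  r <- object@records
  cat("StudyFixture with", nrow(r), "protein records\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(PHYLO_CLASSES),
                    tabulate(factor(r$phylo_class,
                                    levels = names(PHYLO_CLASSES)), 4L)),
            collapse = " "), "\n")
  cat("  hm_similarity: ",
      sprintf("%.1f-%.1f (mean %.1f)", min(r$hm_similarity),
              max(r$hm_similarity), mean(r$hm_similarity)), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: length %d, score %.1f, identity %.1f%%, similarity %.1f%%, %d gap column(s)\n",
    nchar(object@alignedA), object@score, object@percentIdentity,
    object@percentSimilarity, object@gapColumns))
  if (nchar(object@alignedA) <= 70) {
    cat("  ", object@alignedA, "\n  ", object@alignedB, "\n", sep = "")
  }
  invisible(NULL)
})

setMethod("show", "HitProfile", function(object) {
  cat("HitProfile for", object@protein, "\n")
  print(object@hits)
  cat(" ", length(object@homologIds), "homologue id(s)\n")
  invisible(NULL)
})

setMethod("show", "GeneTree", function(object) {
  nd <- object@nodeData
  cat("GeneTree:", length(object@tree$tip.label), "tips,",
      object@tree$Nnode, "internal nodes,",
      sum(nd$isDuplication), "duplication node(s)\n")
  invisible(NULL)
})

setMethod("show", "DuplicationHistory", function(object) {
  cat("DuplicationHistory:", nrow(object@counts), "gene(s) x",
      ncol(object@counts), "taxon bins (",
      object@schedule$taxon[1], "...",
      object@schedule$taxon[nrow(object@schedule)], ")\n")
  invisible(NULL)
})

setMethod("show", "GroupTestResult", function(object) {
  cat(sprintf(
    "GroupTestResult '%s': %d within / %d background pairs, W = %.1f\n",
    object@group, object@nWithinPairs, object@nBackgroundPairs,
    object@uStatistic))
  cat(sprintf("  p = %.4g (Bonferroni %.4g), direction: %s\n",
              object@pRaw, object@pBonferroni, object@direction))
  invisible(NULL)
})
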