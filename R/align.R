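## Column-wise bookkeeping shared by the percent statistics: for each
## alignment column, whether it is a gap column, an identity, or a positive
## substitution-score pair.
alignmentColumns <- function(alignedA, alignedB, matrix = "BLOSUM62") {
  sm <- resolveMatrix(matrix)
  a <- strsplit(alignedA, "", fixed = TRUE)[[1]]
  b <- strsplit(alignedB, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b))
  gap <- a == "-" | b == "-"
  pos <- ident <- logical(length(a))
  if (any(!gap)) {
    ident[!gap] <- a[!gap] == b[!gap]
    pos[!gap] <- sm[cbind(a[!gap], b[!gap])] > 0
  }
  list(n = length(a), gap = gap, identical = ident, positive = pos)
}

#' Global pairwise protein alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment under a substitution matrix (BLOSUM62 by
#' default) with affine gap penalties: a gap of length L costs
#' `gapOpening + L * gapExtension`. End gaps are penalized (true global
#' alignment); `endGapsPenalized = FALSE` switches to end-gap-free
#' (semi-global) semantics. The dynamic programming and traceback are
#' delegated to [Biostrings::pairwiseAlignment()]; the optimal score is the
#' contract, and the reported traceback is the aligner's deterministic one.
#'
#' Percent identity and percent similarity are computed over all alignment
#' columns (gap columns count in the denominator only); a column is "similar"
#' when its residue pair has a positive substitution score.
#'
#' @param seqA,seqB non-empty amino-acid sequences (character or
#'   [Biostrings::AAString]).
#' @param matrix substitution matrix or the name of a Biostrings one
#'   (default `"BLOSUM62"`).
#' @param gapOpening,gapExtension affine gap penalties; defaults 10 and 0.5,
#'   the classical defaults of the EMBOSS/EBI global alignment service.
#' @param endGapsPenalized penalize terminal gaps (default `TRUE`).
#' @return an [AlignmentResult-class].
#' @examples
#' aln <- alignGlobal("HEAGAWGHEE", "PAWHEAE")
#' aln
#' percentSimilarity(aln)
#' @export
alignGlobal <- function(seqA, seqB, matrix = "BLOSUM62", gapOpening = 10,
                        gapExtension = 0.5, endGapsPenalized = TRUE) {
  seqA <- toupper(as.character(seqA))
  seqB <- toupper(as.character(seqB))
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("cannot align an empty sequence")
  sm <- resolveMatrix(matrix)
  res <- unique(strsplit(paste0(seqA, seqB), "")[[1]])
  missing <- setdiff(res, rownames(sm))
  if (length(missing))
    stop("residue(s) absent from the substitution matrix: ",
         paste(missing, collapse = ", "))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = sm, gapOpening = gapOpening,
    gapExtension = gapExtension,
    type = if (endGapsPenalized) "global" else "overlap")
  alignedA <- as.character(Biostrings::alignedPattern(pa))
  alignedB <- as.character(Biostrings::alignedSubject(pa))
  cols <- alignmentColumns(alignedA, alignedB, sm)
  new("AlignmentResult",
      alignedA = alignedA, alignedB = alignedB,
      score = Biostrings::score(pa),
      percentIdentity = 100 * sum(cols$identical) / cols$n,
      percentSimilarity = 100 * sum(cols$positive) / cols$n,
      gapColumns = sum(cols$gap))
}

#' Percent similarity of an alignment
#'
#' 100 x (columns whose residue pair has a positive substitution score) /
#' (total alignment columns, gap columns included in the denominator only).
#' With the default arguments this returns the value stored on the
#' [AlignmentResult-class]; passing a different matrix recomputes it
#' column-by-column.
#'
#' @param alignment an [AlignmentResult-class], or a gapped sequence
#'   (with `alignedB`).
#' @param matrix substitution matrix (default `"BLOSUM62"`).
#' @param alignedB second gapped sequence when `alignment` is a character.
#' @return percent in \[0, 100\].
#' @export
percentSimilarity <- function(alignment, matrix = "BLOSUM62",
                              alignedB = NULL) {
  if (is(alignment, "AlignmentResult")) {
    cols <- alignmentColumns(alignment@alignedA, alignment@alignedB, matrix)
  } else {
    stopifnot(is.character(alignment), !is.null(alignedB))
    cols <- alignmentColumns(alignment, alignedB, matrix)
  }
  100 * sum(cols$positive) / cols$n
}
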