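#' Load a packaged study fixture
#'
#' `loadFixture("gsis69")` returns the 69 protein components of the core
#' glucose-stimulated insulin secretion (GSIS) network as transcribed from
#' the study tables: abbreviation, Swiss-Prot accession, ordered sub-pathway
#' codes, phylogenetic age class, human-mouse percent similarity, plus the
#' per-protein positive-selection episodes and OMIM disease associations.
#' The fixture also carries the genome-wide reference proportions of the four
#' age classes (U 0.56, E 0.20, M 0.05, V 0.19) used by
#' [compareComposition()].
#'
#' @param name fixture identifier; `"gsis69"` is the packaged study cohort.
#' @param dir directory holding the fixture files; defaults to the copies
#'   installed with the package.
#' @return a [StudyFixture-class].
#' @examples
#' fx <- loadFixture("gsis69")
#' fx
#' subset(records(fx), abbrev == "GK")[, c("abbrev", "phylo_class",
#'                                         "hm_similarity")]
#' @export
loadFixture <- function(name = "gsis69", dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", name, package = "gsisEvol")
  if (!nzchar(dir) || !dir.exists(dir))
    stop("unknown fixture name: ", name)
  prot <- utils::read.delim(file.path(dir, "proteins.tsv"),
                            stringsAsFactors = FALSE, check.names = FALSE)
  sel <- utils::read.delim(file.path(dir, "selection.tsv"),
                           stringsAsFactors = FALSE)
  dis <- utils::read.delim(file.path(dir, "disease.tsv"),
                           colClasses = c("character", "character",
                                          "character"))
  info <- jsonlite::read_json(file.path(dir, "fixture_info.json"),
                              simplifyVector = FALSE)
  bad <- setdiff(c(sel$abbrev, dis$abbrev), prot$abbrev)
  if (length(bad))
    stop("selection/disease rows refer to unknown proteins: ",
         paste(unique(bad), collapse = ", "))
  prot$n_duplications <- NA_integer_
  prot$selection <- I(lapply(prot$abbrev, function(a) {
    s <- sel[sel$abbrev == a, c("taxon", "age_mya"), drop = FALSE]
    rownames(s) <- NULL
    s
  }))
  prot$disease <- I(lapply(prot$abbrev, function(a) {
    d <- dis[dis$abbrev == a, c("omim_code", "disease"), drop = FALSE]
    rownames(d) <- NULL
    d
  }))
  ref <- unlist(info$genome_reference_proportions)[names(PHYLO_CLASSES)]
  fx <- new("StudyFixture", records = prot, referenceProportions = ref,
            info = info)
  if (identical(name, "gsis69") && nrow(prot) != 69L)
    stop("gsis69 fixture must contain exactly 69 records")
  fx
}

#' Write a study fixture back to its on-disk TSV/JSON layout
#'
#' Writes `proteins.tsv`, `selection.tsv`, `disease.tsv` and
#' `fixture_info.json` into `dir` in the same dialect [loadFixture()] reads,
#' so that a written fixture re-reads to an identical record set.
#'
#' @param fixture a [StudyFixture-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  stopifnot(is(fixture, "StudyFixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- records(fixture)
  flat <- r[, c("abbrev", "protein_name", "swissprot_id", "pathways",
                "phylo_class", "hm_similarity")]
  utils::write.table(flat, file.path(dir, "proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  unroll <- function(col, names_out) {
    out <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
      d <- r[[col]][[i]]
      if (!NROW(d)) return(NULL)
      cbind(abbrev = r$abbrev[i], d)
    }))
    if (is.null(out))
      out <- stats::setNames(
        as.data.frame(matrix(nrow = 0, ncol = length(names_out))), names_out)
    out
  }
  utils::write.table(unroll("selection", c("abbrev", "taxon", "age_mya")),
                     file.path(dir, "selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(unroll("disease", c("abbrev", "omim_code", "disease")),
                     file.path(dir, "disease.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  info <- fixtureInfo(fixture)
  info$genome_reference_proportions <- as.list(referenceProportions(fixture))
  jsonlite::write_json(info, file.path(dir, "fixture_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Disease- and selection-flag helpers
#'
#' `hasDisease()` flags records with at least one OMIM association;
#' `hasSelection()` flags records with at least one positive-selection
#' episode.
#'
#' @param x a [StudyFixture-class] or records data.frame.
#' @return logical vector along the records.
#' @export
hasDisease <- function(x) {
  r <- asRecords(x)
  if (!"disease" %in% names(r)) return(rep(FALSE, nrow(r)))
  vapply(r$disease, NROW, 1L) > 0L
}

#' @rdname hasDisease
#' @export
hasSelection <- function(x) {
  r <- asRecords(x)
  if (!"selection" %in% names(r)) return(rep(FALSE, nrow(r)))
  vapply(r$selection, NROW, 1L) > 0L
}
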