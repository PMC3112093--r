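#' Read a protein FASTA file
#'
#' Sequences are uppercased; identifiers are the first whitespace-delimited
#' token of each header. In `strict` mode residues outside the 20 standard
#' amino acids plus `X` are an error; in lenient mode anything the amino-acid
#' alphabet can represent is kept.
#'
#' @param path FASTA file.
#' @param strict validate residues (default `TRUE`).
#' @return a named [Biostrings::AAStringSet].
#' @export
readFasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (strict) {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
    if (any(bad))
      stop("non-amino-acid characters in sequence(s): ",
           paste(names(seqs)[bad], collapse = ", "),
           " (use strict = FALSE to keep them)")
  }
  Biostrings::AAStringSet(seqs)
}

#' Write sequences as FASTA
#'
#' Canonical dialect: `>id` headers and 60-column sequence lines, so that
#' reading a written file and re-writing it is byte-identical.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet].
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a tabular homology-hit file
#'
#' The canonical dialect is tab-separated with a header and columns `query`,
#' `genome`, `category` (one of `prokaryote`, `nonmetazoan_eukaryote`,
#' `nonmammalian_metazoan`, `vertebrate`, `mammal`), `evalue`, and an
#' optional `subject` column carrying the subject sequence identifier. Rows
#' with E-value above `cutoff` are dropped and only the best (smallest
#' E-value) hit per query/genome pair is retained.
#'
#' @param path hit table file.
#' @param cutoff E-value cutoff (default 10, the screening threshold of the
#'   profile construction).
#' @return data.frame of retained hits.
#' @export
readHitTable <- function(path, cutoff = 10) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("query", "genome", "category", "evalue")
  if (!all(needed %in% names(tab)))
    stop("hit table needs columns: ", paste(needed, collapse = ", "))
  if (!is.numeric(tab$evalue)) {
    ev <- suppressWarnings(as.numeric(tab$evalue))
    if (anyNA(ev)) stop("malformed E-value(s) in hit table")
    tab$evalue <- ev
  }
  if (anyNA(tab$evalue)) stop("malformed E-value(s) in hit table")
  bad <- setdiff(unique(tab$category), HIT_CATEGORIES)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  tab <- tab[tab$evalue <= cutoff, , drop = FALSE]
  if (nrow(tab)) {
    ord <- order(tab$query, tab$genome, tab$evalue)
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(tab[, c("query", "genome")]), , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "cutoff") <- cutoff
  tab
}

#' Write a hit table in the canonical dialect
#' @param tab data.frame as returned by [readHitTable()].
#' @param path output file.
#' @export
writeHitTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build per-protein hit profiles from a hit table
#'
#' Counts distinct genomes hit per taxonomic category; hits whose category is
#' `mammal` are collapsed into `vertebrate` (the age classification treats
#' vertebrate as the terminal class). Homologue identifiers are taken from
#' the `subject` column when present, otherwise the genome identifiers are
#' used.
#'
#' @param tab a hit table data.frame (see [readHitTable()]).
#' @return named list of [HitProfile-class], one per query protein.
#' @export
buildHitProfiles <- function(tab) {
  cat4 <- ifelse(tab$category == "mammal", "vertebrate", tab$category)
  idcol <- if ("subject" %in% names(tab)) tab$subject else tab$genome
  out <- lapply(split(seq_len(nrow(tab)), tab$query), function(i) {
    counts <- vapply(PROFILE_CATEGORIES, function(cc)
      length(unique(tab$genome[i][cat4[i] == cc])), 1L)
    new("HitProfile", protein = tab$query[i[1]],
        hits = stats::setNames(as.integer(counts), PROFILE_CATEGORIES),
        homologIds = unique(idcol[i]))
  })
  out[order(names(out))]
}

## ---- Newick/NHX gene trees -------------------------------------------------

## Split an NHX comment body ("D=Y:T=Euteleostomi:A=420") into a named list.
parseNhxTags <- function(body) {
  body <- sub("^&&NHX:?", "", body)
  if (!nzchar(body)) return(list())
  kv <- strsplit(strsplit(body, ":", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) >= 2) p[2] else NA_character_)
  stats::setNames(vals, vapply(kv, `[`, "", 1L))
}

#' Read a Newick/NHX gene tree with duplication annotations
#'
#' Internal nodes (and tips) may carry NHX comments of the form
#' `[&&NHX:D=Y:T=Euteleostomi:A=420]`: `D=Y` flags a duplication node, `T=`
#' gives its taxon label, `A=` its age in MYA and `F=Y` marks the node as the
#' founder of a new gene family (truncating duplication-history extraction).
#' Unknown tags are ignored. Un-annotated nodes default to
#' non-duplication/unknown taxon.
#'
#' @param path file containing one Newick/NHX tree, or a tree string ending
#'   in `;`.
#' @return a [GeneTree-class].
#' @export
readGeneTree <- function(path) {
  txt <- if (grepl(";\\s*$", path) && !file.exists(path)) path
         else paste(readLines(path, warn = FALSE), collapse = "")
  ## pull NHX comments out, leaving numbered markers in label position
  tags <- list()
  repeat {
    m <- regexpr("\\[&&NHX[^]]*\\]", txt)
    if (m == -1L) break
    body <- substr(txt, m + 1L, m + attr(m, "match.length") - 2L)
    tags[[length(tags) + 1L]] <- parseNhxTags(body)
    txt <- paste0(substr(txt, 1L, m - 1L),
                  sprintf("__NHX%d", length(tags)),
                  substr(txt, m + attr(m, "match.length"), nchar(txt)))
  }
  bare <- gsub("\\[[^]]*\\]", "", txt)  # drop any remaining comments
  if (lengths(regmatches(bare, gregexpr("(", bare, fixed = TRUE))) !=
      lengths(regmatches(bare, gregexpr(")", bare, fixed = TRUE))))
    stop("unbalanced parentheses in tree")
  phy <- ape::read.tree(text = bare)
  if (is.null(phy)) stop("could not parse tree")
  nTip <- length(phy$tip.label)
  labs <- c(phy$tip.label,
            if (!is.null(phy$node.label)) phy$node.label
            else rep("", phy$Nnode))
  labs[is.na(labs)] <- ""
  idx <- rep(NA_integer_, length(labs))
  has <- grepl("__NHX([0-9]+)$", labs)
  idx[has] <- as.integer(sub(".*__NHX([0-9]+)$", "\\1", labs[has]))
  labs <- sub("__NHX[0-9]+$", "", labs)
  phy$tip.label <- labs[seq_len(nTip)]
  if (anyDuplicated(phy$tip.label))
    stop("duplicated leaf names: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  phy$node.label <- labs[-seq_len(nTip)]
  tagAt <- function(i, key) {
    if (is.na(idx[i])) return(NA_character_)
    v <- tags[[idx[i]]][[key]]
    if (is.null(v)) NA_character_ else v
  }
  n <- nTip + phy$Nnode
  nodeData <- data.frame(
    node = seq_len(n),
    isDuplication = vapply(seq_len(n), function(i)
      identical(tagAt(i, "D"), "Y"), TRUE),
    taxon = vapply(seq_len(n), function(i) tagAt(i, "T"), ""),
    age = suppressWarnings(as.numeric(
      vapply(seq_len(n), function(i) tagAt(i, "A"), ""))),
    familyFounder = vapply(seq_len(n), function(i)
      identical(tagAt(i, "F"), "Y"), TRUE),
    stringsAsFactors = FALSE)
  new("GeneTree", tree = phy, nodeData = nodeData)
}

#' Write a gene tree in the canonical NHX dialect
#'
#' Emits Newick with `[&&NHX:...]` comments (keys in the order `D`, `T`,
#' `A`, `F`) on every node that carries annotation, so that reading a
#' written file and re-writing it round-trips byte-identically.
#'
#' @param gt a [GeneTree-class].
#' @param path output file, or `NULL` to return the tree string.
#' @export
writeGeneTree <- function(gt, path = NULL) {
  stopifnot(is(gt, "GeneTree"))
  phy <- gt@tree
  nd <- gt@nodeData
  nTip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  tagStr <- function(i) {
    parts <- character(0)
    if (nd$isDuplication[i] || !is.na(nd$taxon[i]) || !is.na(nd$age[i]) ||
        nd$familyFounder[i]) {
      parts <- c(parts, paste0("D=", if (nd$isDuplication[i]) "Y" else "N"))
      if (!is.na(nd$taxon[i]) && nzchar(nd$taxon[i]))
        parts <- c(parts, paste0("T=", nd$taxon[i]))
      if (!is.na(nd$age[i]))
        parts <- c(parts, paste0("A=", format(nd$age[i], trim = TRUE)))
      if (nd$familyFounder[i]) parts <- c(parts, "F=Y")
    }
    if (!length(parts)) "" else paste0("[&&NHX:", paste(parts, collapse = ":"), "]")
  }
  recurse <- function(i) {
    if (i <= nTip) return(paste0(phy$tip.label[i], tagStr(i)))
    lab <- if (!is.null(phy$node.label)) phy$node.label[i - nTip] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(vapply(kids[[as.character(i)]], recurse, ""),
                      collapse = ","), ")", lab, tagStr(i))
  }
  out <- paste0(recurse(nTip + 1L), ";")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}
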