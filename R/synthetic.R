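AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Default synthetic-cohort group specification
#'
#' One row per primary-pathway group with the group sizes and the
#' means/standard deviations of human-mouse percent similarity observed in
#' the packaged study cohort — so a default synthetic cohort emulates the
#' statistical structure of the real one (69 proteins, two conservation
#' coalitions).
#'
#' @return data.frame with columns `group`, `size`, `mean`, `sd`.
#' @export
defaultGroupSpec <- function() {
  data.frame(
    group = c("G", "T", "P", "N", "M", "R", "S"),
    size = c(11L, 16L, 4L, 6L, 2L, 24L, 6L),
    mean = c(97.9, 95.9, 92.8, 96.4, 97.9, 91.0, 88.7),
    sd = c(1.5, 3.6, 7.3, 2.1, 2.0, 3.4, 7.1),
    stringsAsFactors = FALSE)
}

#' Synthesize a protein pair with a target percent similarity
#'
#' Draws a random amino-acid sequence and derives a partner by substituting
#' residues (preferring replacements with non-positive BLOSUM62 score, so
#' each substitution removes one "similar" column) and introducing
#' occasional single-residue deletions. The realized similarity — measured
#' by [alignGlobal()] / [percentSimilarity()] — is tuned to within +-2
#' points of the target by a bounded rejection loop that adapts the
#' substitution count between retries.
#'
#' @param length sequence length (>= 10).
#' @param targetSimilarity target percent in \[50, 100\].
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @param indelRate per-site deletion probability (default 0.005).
#' @param maxRetries rejection-loop bound (default 50).
#' @return list with `seqA`, `seqB`, `realized` (measured percent
#'   similarity).
#' @export
synthProteinPair <- function(length, targetSimilarity, seed = NULL,
                             indelRate = 0.005, maxRetries = 50L) {
  if (length < 10L) stop("length must be >= 10")
  if (targetSimilarity < 50 || targetSimilarity > 100)
    stop("targetSimilarity must lie in [50, 100]")
  withSeed(seed, {
    sm <- resolveMatrix("BLOSUM62")
    negChoices <- lapply(AA20, function(a)
      AA20[sm[a, AA20] <= 0])
    names(negChoices) <- AA20
    seqA <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    if (targetSimilarity == 100)
      return(list(seqA = seqA, seqB = seqA, realized = 100))
    k <- round(length * (1 - targetSimilarity / 100))
    for (try in seq_len(maxRetries)) {
      chars <- strsplit(seqA, "")[[1]]
      pos <- sample(length, min(max(k, 0L), length))
      for (p in pos) chars[p] <- sample(negChoices[[chars[p]]], 1L)
      nDel <- stats::rbinom(1L, length, indelRate)
      if (nDel > 0)
        chars <- chars[-sample(seq_along(chars), nDel)]
      seqB <- paste(chars, collapse = "")
      realized <- percentSimilarity(alignGlobal(seqA, seqB))
      if (abs(realized - targetSimilarity) <= 2)
        return(list(seqA = seqA, seqB = seqB, realized = realized))
      k <- max(0L, min(length,
                       k + round(length * (realized - targetSimilarity) / 100)))
    }
    stop("could not reach target similarity ", targetSimilarity,
         " within ", maxRetries, " retries")
  })
}

#' Synthesize a hit profile with a known phylogenetic class
#'
#' Draws category hit counts under hard constraints so that
#' [classifyProfile()] recovers `trueClass` with probability 1: Universal
#' profiles get more than five prokaryote hits; Eukaryote-specific at most
#' five prokaryote and at least one non-metazoan-eukaryote hit;
#' Metazoan-specific no eukaryote hit but at least one non-mammalian
#' metazoan; Vertebrate-specific hits nothing outside vertebrates.
#'
#' @param trueClass one of `"U"`, `"E"`, `"M"`, `"V"`.
#' @param seed RNG seed (`NULL` = current state).
#' @param maxCount upper bound for drawn counts (default 10).
#' @param nHomologs number of random homologue ids to attach (default 0).
#' @param protein profile name (default `"synth"`).
#' @return a [HitProfile-class].
#' @export
synthHitProfile <- function(trueClass = c("U", "E", "M", "V"), seed = NULL,
                            maxCount = 10L, nHomologs = 0L,
                            protein = "synth") {
  trueClass <- match.arg(trueClass)
  withSeed(seed, {
    rc <- function(lo, hi) sample(seq.int(lo, hi), 1L)
    h <- switch(trueClass,
      U = c(rc(6L, max(6L, maxCount)), rc(0L, maxCount), rc(0L, maxCount),
            rc(0L, maxCount)),
      E = c(rc(0L, 5L), rc(1L, maxCount), rc(0L, maxCount), rc(0L, maxCount)),
      M = c(rc(0L, 5L), 0L, rc(1L, maxCount), rc(0L, maxCount)),
      V = c(0L, 0L, 0L, rc(0L, maxCount)))
    ids <- if (nHomologs > 0)
      sprintf("h%05d", sample.int(99999L, nHomologs)) else character(0)
    new("HitProfile", protein = protein,
        hits = stats::setNames(as.integer(h), PROFILE_CATEGORIES),
        homologIds = ids)
  })
}

#' Synthesize a duplication-annotated gene tree with known ground truth
#'
#' Builds a ladderized gene tree along the focal lineage: walking the bin
#' schedule from oldest to youngest, each bin contributes one speciation
#' node (with a species sister leaf) and a Poisson-distributed number of
#' duplication nodes, each emitting a paralog leaf and annotated
#' `D=Y:T=<taxon>:A=<age>` in NHX. The drawn per-bin counts are returned as
#' the ground-truth duplication vector, which
#' [extractDuplicationVector()] must recover exactly.
#'
#' @param focal focal leaf label (default `"focal"`).
#' @param schedule taxon/age bins (default [defaultTaxonSchedule()]).
#' @param dupRates per-bin Poisson rates, recycled to the schedule length
#'   (default 0.3).
#' @param seed RNG seed (`NULL` = current state).
#' @return list with `newick` (NHX string), `tree` (a
#'   [GeneTree-class]), and `truth` (named ground-truth counts).
#' @export
synthGeneTree <- function(focal = "focal", schedule = defaultTaxonSchedule(),
                          dupRates = 0.3, seed = NULL) {
  stopifnot(nrow(schedule) >= 1L)
  rates <- rep_len(dupRates, nrow(schedule))
  withSeed(seed, {
    counts <- stats::rpois(nrow(schedule), rates)
    cur <- focal
    ## youngest bin closest to the focal leaf
    for (i in rev(seq_len(nrow(schedule)))) {
      tax <- schedule$taxon[i]
      age <- schedule$age[i]
      if (counts[i] > 0) for (j in seq_len(counts[i]))
        cur <- sprintf("(%s,dup_%s_%d)[&&NHX:D=Y:T=%s:A=%s]",
                       cur, tax, j, tax, format(age, trim = TRUE))
      cur <- sprintf("(%s,sp_%s)[&&NHX:D=N:T=%s:A=%s]",
                     cur, tolower(tax), tax, format(age, trim = TRUE))
    }
    newick <- sprintf("(%s,outgroup);", cur)
    list(newick = newick, tree = readGeneTree(newick),
         truth = stats::setNames(as.integer(counts), schedule$taxon))
  })
}

#' Synthesize a protein cohort with known group effects and rank
#' correlation
#'
#' Draws per-group Gaussian similarities (truncated to \[0, 100\]) and
#' duplication counts linked to similarity through a Gaussian copula
#' targeting a stated Spearman correlation (the Pearson parameter is
#' `2 sin(pi rho / 6)`, the exact normal-copula inversion); counts are then
#' Poisson quantiles. Phylogenetic classes are drawn with the study cohort's
#' proportions (77/17/3/3). The defaults emulate the study cohort's group
#' structure ([defaultGroupSpec()]) and its printed divergence-duplication
#' rank correlation (rho = 0.339).
#'
#' @param groupSpec data.frame with `group` (pathway codes), `size`, `mean`,
#'   `sd` (default [defaultGroupSpec()]).
#' @param rho target Spearman correlation between similarity and
#'   duplication count (default 0.339).
#' @param dupLambda Poisson mean of duplication counts, scalar or per-group
#'   (default 3).
#' @param seed RNG seed (`NULL` = current state).
#' @return records data.frame (as in [StudyFixture-class]) with ground
#'   truth in `attr(, "truth")`.
#' @export
synthCohort <- function(groupSpec = defaultGroupSpec(), rho = 0.339,
                        dupLambda = 3, seed = NULL) {
  stopifnot(nrow(groupSpec) >= 1L, all(groupSpec$size >= 1L),
            all(groupSpec$sd >= 0), abs(rho) < 1)
  if (!all(groupSpec$group %in% names(PATHWAY_CODES)))
    stop("groupSpec groups must be pathway codes (",
         paste(names(PATHWAY_CODES), collapse = ", "), ")")
  lambda <- rep_len(dupLambda, nrow(groupSpec))
  withSeed(seed, {
    rPearson <- 2 * sin(pi * rho / 6)
    rows <- lapply(seq_len(nrow(groupSpec)), function(i) {
      n <- groupSpec$size[i]
      z1 <- stats::rnorm(n)
      z2 <- rPearson * z1 + sqrt(1 - rPearson^2) * stats::rnorm(n)
      sim <- pmin(100, pmax(0, groupSpec$mean[i] + groupSpec$sd[i] * z1))
      dup <- stats::qpois(stats::pnorm(z2), lambda[i])
      data.frame(group = groupSpec$group[i], hm_similarity = sim,
                 n_duplications = as.integer(dup),
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    n <- nrow(d)
    recs <- data.frame(
      abbrev = sprintf("g%03d", seq_len(n)),
      protein_name = sprintf("synthetic protein %d", seq_len(n)),
      swissprot_id = sprintf("X%05d", seq_len(n)),
      pathways = d$group,
      phylo_class = sample(names(PHYLO_CLASSES), n, replace = TRUE,
                           prob = c(0.77, 0.17, 0.03, 0.03)),
      hm_similarity = d$hm_similarity,
      n_duplications = d$n_duplications,
      stringsAsFactors = FALSE)
    recs$selection <- I(replicate(n, data.frame(taxon = character(0),
                                                age_mya = numeric(0)),
                                  simplify = FALSE))
    recs$disease <- I(replicate(n, data.frame(omim_code = character(0),
                                              disease = character(0)),
                                simplify = FALSE))
    attr(recs, "truth") <- list(groupSpec = groupSpec, rho = rho,
                                dupLambda = lambda)
    recs
  })
}
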