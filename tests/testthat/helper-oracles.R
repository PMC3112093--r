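## Independent oracles used to cross-check the implementation. These are
## deliberately naive re-derivations (explicit recurrences, brute-force
## scans, union-find) and share no code with the package internals.

.blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

randomAASeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                 collapse = "")

## Exhaustive three-state (match / gap-in-b / gap-in-a) affine-gap global
## dynamic programme; a gap of length L costs open + L * ext, end gaps
## penalized.
nwOracle <- function(a, b, sm = .blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- sm[A[i], B[j]] + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                           X[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## Column-by-column hand count of positive-score columns.
similarityScanOracle <- function(alignedA, alignedB, sm = .blosum62) {
  a <- strsplit(alignedA, "")[[1]]
  b <- strsplit(alignedB, "")[[1]]
  hits <- 0
  for (i in seq_along(a)) {
    if (a[i] != "-" && b[i] != "-" && sm[a[i], b[i]] > 0) hits <- hits + 1
  }
  100 * hits / length(a)
}

## Union-find connected components over shared-homologue edges.
unionFindOracle <- function(idSets, minShared) {
  n <- length(idSets)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j &&
        length(intersect(idSets[[i]], idSets[[j]])) >= minShared) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, 1L)
}

## Tukey fences computed longhand with interpolated quartiles.
fenceOracle <- function(v) {
  s <- sort(v)
  interp <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  q1 <- interp(0.25)
  q3 <- interp(0.75)
  c(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1))
}

## Small synthetic cohort builder for stats tests: explicit values + flags.
makeRecords <- function(sim, pathways = rep("G", length(sim)),
                        class = rep("U", length(sim)),
                        disease = rep(FALSE, length(sim)),
                        selection = rep(FALSE, length(sim))) {
  n <- length(sim)
  data.frame(
    abbrev = sprintf("p%02d", seq_len(n)),
    protein_name = sprintf("protein %d", seq_len(n)),
    swissprot_id = sprintf("Q%05d", seq_len(n)),
    pathways = pathways, phylo_class = class, hm_similarity = sim,
    n_duplications = rep(NA_integer_, n),
    selection = I(lapply(selection, function(s)
      if (s) data.frame(taxon = "Euteleostomi", age_mya = 420)
      else data.frame(taxon = character(0), age_mya = numeric(0)))),
    disease = I(lapply(disease, function(d)
      if (d) data.frame(omim_code = "123456", disease = "synthetic")
      else data.frame(omim_code = character(0), disease = character(0)))),
    stringsAsFactors = FALSE)
}
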