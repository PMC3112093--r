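## Internal helpers shared across modules.

## Run code under a fixed RNG seed without disturbing the caller's RNG state.
## seed = NULL leaves the RNG alone.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Accept either a StudyFixture or a bare records data.frame.
asRecords <- function(x) {
  if (is(x, "StudyFixture")) return(records(x))
  if (is.data.frame(x)) return(x)
  stop("expected a StudyFixture or a protein records data.frame")
}

## First-listed pathway code of each record (the primary pathway).
primaryPathway <- function(recs) {
  trimws(sub(",.*", "", recs$pathways))
}

## Pairwise index helper: rows i < j of an n x n matrix.
pairIndices <- function(idx) {
  if (length(idx) < 2L) return(matrix(integer(0), ncol = 2))
  t(combn(sort(idx), 2L))
}

## Resolve a substitution matrix argument: either a named matrix or the name
## of one of the matrices shipped with Biostrings (e.g. "BLOSUM62").
resolveMatrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  if (is.character(matrix) && length(matrix) == 1L) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    return(get(matrix, envir = env))
  }
  stop("substitution matrix must be a matrix or the name of a Biostrings one")
}

logMsg <- function(...) message("[gsisEvol] ", ...)
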