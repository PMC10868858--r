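#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so that every stochastic operation in the package
#' is reproducible per call without disturbing the session.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random nucleotide sequence
#' @param len sequence length.
#' @return A single character string over ACGT.
#' @keywords internal
random_seq <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Mutate a sequence at a fixed number of positions (substitutions only)
#' @keywords internal
substitute_at <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Hamming distance between two equal-length sequences
#' @param a,b character strings of equal length.
#' @return integer count of differing positions.
#' @export
hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("hamming() requires equal-length sequences")
  sum(ca != cb)
}

# Greek letters used in cidA upstream-region nomenclature (stored as
# \u escapes so the sources stay ASCII).
greek <- c(alpha = "\u03b1", beta = "\u03b2", gamma = "\u03b3",
           delta = "\u03b4", epsilon = "\u03b5", zeta = "\u03b6",
           eta = "\u03b7", theta = "\u03b8")
greek_alphabet <- unname(c(greek, "\u03b9", "\u03ba", "\u03bb", "\u03bc"))

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x
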