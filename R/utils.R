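# Shared low-level helpers: alphabet checks, reverse complement, IUPAC codes.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> the set of bases each code stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the ACGTN alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, extra = "N", what = "sequence") {
  allowed <- c(DNA_BASES, extra)
  bad <- grepl(sprintf("[^%s]", paste(allowed, collapse = "")), toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}",
                 what, paste(allowed, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

# Split sequences of equal length into an n x L character matrix.
seq_char_matrix <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length", call. = FALSE)
  matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
         nrow = length(sequences), ncol = L, byrow = TRUE)
}

# Deterministic child seed derived from a base seed and a stream label.
# Kept below 2^31 so it is a valid R integer.
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream))) %% 1000L
  (as.integer(seed) * 1009L + s * 97L) %% 2147483629L
}

# Collapse the rows of a character matrix into strings (fast paste0 over
# columns; avoids per-row apply on large read sets).
collapse_rows <- function(mat) {
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}
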