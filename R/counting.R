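# Exact-match variant counting and coverage filtering.
#
# Reads report their own insert; a read (pair) is assigned to a variant only
# if the insert region matches a library insert exactly in length and
# nucleotide composition.  Duplicates are retained by design: read counts are
# the quantitative signal.

#' Count exact insert matches per variant and sample
#'
#' For each sample the insert region is extracted from read 1 (and, in
#' strict mode, from the reverse complement of read 2) at the template's
#' insert coordinates and matched against the library's full insert
#' sequences.  Any mismatch — in fixed or degenerate positions — or length
#' deviation discards the read; in strict mode disagreeing mates discard the
#' pair.  No deduplication is performed.
#'
#' @param samples data.frame with columns `sample_id`, `fastq1` and (for
#'   strict mode) `fastq2`, e.g. from [simulate_reads()] or
#'   [read_sample_sheet()].
#' @param library a `variant_library`.
#' @param mate_mode `"strict"` (default: mates must agree on the insert) or
#'   `"read1"` (read 1 only).
#' @return integer count matrix (library variants x samples) with a
#'   `tallies` attribute: per-sample data.frame of total, assigned and
#'   discarded read (pair) counts.
#' @export
count_exact_matches <- function(samples, library,
                                mate_mode = c("strict", "read1")) {
  mate_mode <- match.arg(mate_mode)
  stopifnot(inherits(library, "variant_library"),
            all(c("sample_id", "fastq1") %in% names(samples)))
  if (length(library$keys) == 0L) stop("empty library", call. = FALSE)
  tpl <- library$template
  inserts <- variant_insert(tpl, library$keys)
  counts <- matrix(0L, length(library$keys), nrow(samples),
                   dimnames = list(library$keys, samples$sample_id))
  tallies <- data.frame(sample_id = samples$sample_id, total = 0L,
                        assigned = 0L, discarded = 0L,
                        stringsAsFactors = FALSE)
  oligo_len <- nchar(tpl$full_sequence)
  for (j in seq_len(nrow(samples))) {
    r1 <- read_fastq_seqs(samples$fastq1[j])
    n_total <- length(r1)
    ins1 <- extract_insert(r1, tpl, oligo_len)
    idx <- match(ins1, inserts)
    if (mate_mode == "strict") {
      if (!"fastq2" %in% names(samples) || is.na(samples$fastq2[j])) {
        stop("strict mate mode requires fastq2", call. = FALSE)
      }
      r2 <- revcomp(read_fastq_seqs(samples$fastq2[j]))
      if (length(r2) != n_total) {
        stop(sprintf("mate files for %s differ in read count",
                     samples$sample_id[j]), call. = FALSE)
      }
      ins2 <- extract_insert(r2, tpl, oligo_len)
      idx[is.na(ins2) | ins1 != ins2] <- NA_integer_
    }
    hits <- idx[!is.na(idx)]
    if (length(hits)) {
      tab <- tabulate(hits, nbins = length(inserts))
      counts[, j] <- as.integer(tab)
    }
    tallies$total[j] <- n_total
    tallies$assigned[j] <- length(hits)
    tallies$discarded[j] <- n_total - length(hits)
  }
  attr(counts, "tallies") <- tallies
  attr(counts, "filters") <- character(0)
  counts
}

read_fastq_seqs <- function(path) {
  if (file.size(path) == 0) return(character(0))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop(sprintf("malformed FASTQ '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines != 4L * length(x)) {
    stop(sprintf("malformed FASTQ '%s': %d lines for %d records (record %d truncated)",
                 path, n_lines, length(x), length(x)), call. = FALSE)
  }
  as.character(x)
}

# Insert region at the template's coordinates; NA for reads of the wrong
# length (no indel rescue: exactness is the filter).
extract_insert <- function(reads, tpl, oligo_len) {
  out <- rep(NA_character_, length(reads))
  ok <- nchar(reads) == oligo_len
  out[ok] <- substr(reads[ok], tpl$insert_start, tpl$insert_end)
  out
}

#' Number of detected variants
#'
#' @param counts count matrix (variants x samples).
#' @return number of variants with total count >= 1 across all samples.
#' @export
detected_variants <- function(counts) {
  sum(rowSums(counts) >= 1L)
}

#' Drop variants with low mean coverage
#'
#' Retains variants whose mean count across all samples (both conditions)
#' is strictly above `threshold` — the screen's guard against
#' poorly-reproducible low-coverage variants.
#'
#' @param counts count matrix.
#' @param threshold mean-count cutoff (strict `>`), default 100.
#' @return filtered matrix; the applied filter is appended to the `filters`
#'   attribute.
#' @export
filter_min_mean_count <- function(counts, threshold = 100) {
  stopifnot(threshold >= 0)
  keep <- rowMeans(counts) > threshold
  out <- counts[keep, , drop = FALSE]
  attr(out, "tallies") <- attr(counts, "tallies")
  attr(out, "filters") <- c(attr(counts, "filters"),
                            sprintf("mean_count>%g", threshold))
  out
}
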