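# Plain-text artifact readers/writers and the end-to-end screen driver.
# All pipeline artifacts are TSV/CSV/JSON so every stage is inspectable and
# diffable; provenance (seed, parameters) travels in a JSON run report.

#' Read a sample sheet TSV
#'
#' Columns: `sample_id`, `condition` (dex / vehicle), `replicate`, and
#' optionally `fastq1`, `fastq2`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "condition", "replicate")
  if (!all(needed %in% names(df))) {
    stop(sprintf("sample sheet needs columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  df
}

#' Write / read a count matrix TSV
#'
#' Layout: first column `key`, then one integer column per sample.
#'
#' @param counts integer matrix (variants x samples).
#' @param path TSV path.
#' @return the path (write) or the matrix with tallies dropped (read).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(key = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$key
  m
}

#' Write differential results as TSV
#'
#' Standard differential-output columns (key, baseMean, log2FoldChange,
#' lfcSE, stat, pvalue, padj, class).
#'
#' @param results data.frame from [classify_variants()].
#' @param path TSV path.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' @param x named list of provenance and tallies.
#' @param path JSON path.
#' @export
write_run_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' End-to-end simulated screen analysis
#'
#' Runs the full chain simulate -> (optionally reads -> count) ->
#' normalise -> test -> classify and compares calls against the simulation
#' truth.
#'
#' @param config a [screen_sim_config()].
#' @param via_reads also write FASTQ and re-count (slower; default FALSE
#'   tests the statistics directly on the simulated matrix).
#' @param alpha adjusted-p cutoff for classification.
#' @param reads_dir directory for FASTQ files when `via_reads`.
#' @param error_rate read error rate when `via_reads`.
#' @return list with `screen`, `results`, `confusion` (truth class x
#'   called class), `sensitivity` and `fdr` of the significant calls.
#' @export
run_flank_screen <- function(config, via_reads = FALSE, alpha = 0.01,
                             reads_dir = tempfile("reads"),
                             error_rate = 0) {
  screen <- simulate_screen(config)
  counts <- screen$counts
  if (via_reads) {
    files <- simulate_reads(screen, dir = reads_dir,
                            error_rate = error_rate,
                            seed = child_seed(config$seed, "reads"))
    counts <- count_exact_matches(files, config$library)
  }
  res <- differential_activity(counts, screen$samples, alpha = alpha,
                               mode = "flank")
  truth <- screen$truth[match(res$key, screen$truth$key), ]
  confusion <- table(truth = truth$class, called = res$class)
  called_pos <- res$class != "neutral"
  true_pos <- truth$class != "neutral"
  sens <- if (any(true_pos)) {
    sum(called_pos & true_pos &
          sign(res$log2FoldChange) == sign(truth$beta)) / sum(true_pos)
  } else NA_real_
  fdr <- if (any(called_pos)) {
    sum(called_pos & !true_pos) / sum(called_pos)
  } else 0
  list(screen = screen, counts = counts, results = res,
       confusion = confusion, sensitivity = sens, fdr = fdr)
}

#' Count, filter and classify an arbitrary set of screen FASTQ files
#'
#' The real-data entry point: exact-match counting against a library,
#' detection tally, strict mean-count filter and NB classification —
#' the chain behind the screen's reported variant counts.
#'
#' @param samples sample sheet with fastq paths (see
#'   [read_sample_sheet()]).
#' @param library a `variant_library`.
#' @param min_mean_count strict mean-count filter threshold; NA disables
#'   (flank libraries were analysed unfiltered).
#' @param alpha adjusted-p cutoff.
#' @param mode classification mode.
#' @return list with `counts`, `n_detected`, `n_filtered`, `results` and
#'   `class_counts`.
#' @export
reproduce_screen_counts <- function(samples, library,
                                    min_mean_count = 100, alpha = 0.01,
                                    mode = "halfsite") {
  counts <- count_exact_matches(samples, library)
  n_detected <- detected_variants(counts)
  filtered <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (!is.na(min_mean_count)) {
    filtered <- filter_min_mean_count(filtered, min_mean_count)
  }
  res <- differential_activity(filtered, samples, alpha = alpha,
                               mode = mode)
  list(counts = counts, n_detected = n_detected,
       n_filtered = nrow(filtered), results = res,
       class_counts = attr(res, "class_counts"))
}
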