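# Sequence-level activity summaries: ranked colour charts, consensus motifs,
# weighted activity logos, positional group tests and PWM log-odds scoring.

#' Rank variants by estimated activity
#'
#' Descending order by log2 fold change, ties broken lexicographically by
#' key; the returned colour-chart matrix holds the per-position base of each
#' insert in rank order (plot-ready).
#'
#' @param results data.frame with `key` and `log2FoldChange`.
#' @param library a `variant_library` (for insert reconstruction); if NULL,
#'   the chart holds the keys' own bases.
#' @return list with `ranked` (the reordered results) and `chart`
#'   (character matrix, variants x positions).
#' @export
rank_variants <- function(results, library = NULL) {
  o <- order(-results$log2FoldChange, results$key)
  ranked <- results[o, , drop = FALSE]
  seqs <- if (is.null(library)) ranked$key else
    variant_insert(library$template, ranked$key)
  chart <- seq_char_matrix(seqs)
  rownames(chart) <- ranked$key
  list(ranked = ranked, chart = chart)
}

#' Position frequency matrix and information content of a sequence set
#'
#' @param sequences character vector of equal-length DNA sequences.
#' @return a `consensus_motif`: list with `pfm` (positions x ACGT
#'   probabilities), `ic` (per-position information content in bits) and
#'   `n`.
#' @export
consensus_motif <- function(sequences) {
  if (length(sequences) < 1L) stop("need >= 1 sequence", call. = FALSE)
  assert_dna(sequences, extra = character(0))
  mat <- seq_char_matrix(sequences)
  pfm <- t(apply(mat, 2L, function(col) {
    tabulate(factor(col, levels = DNA_BASES), nbins = 4L)
  })) / nrow(mat)
  colnames(pfm) <- DNA_BASES
  ic <- apply(pfm, 1L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(pfm = pfm, ic = ic, n = length(sequences)),
            class = "consensus_motif")
}

# One-sided Mann-Whitney p-values (normal approximation with tie and
# continuity correction) for group membership vs weight.  Returns
# c(p_greater, p_less): P(group weights tend larger / smaller).
mw_onesided <- function(ranks, in_group, tie_term, n) {
  n1 <- sum(in_group)
  n2 <- n - n1
  if (n1 == 0L || n2 == 0L) return(c(NA_real_, NA_real_))
  u <- sum(ranks[in_group]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
  if (sigma == 0) return(c(1, 1))
  p_greater <- stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE)
  p_less <- stats::pnorm((u - mu + 0.5) / sigma, lower.tail = TRUE)
  c(min(p_greater, 1), min(p_less, 1))
}

#' Weighted activity logo
#'
#' For every (position, base) cell, the variants carrying that base are
#' compared against all others by one-sided Mann-Whitney rank tests on the
#' activity weights, in both directions.  Cells with an empty partition are
#' undefined.  Cells at raw p < `highlight` are flagged significant (no
#' multiple-testing correction on the logo, matching the convention of
#' probability logos for weighted sequences).
#'
#' @param sequences equal-length sequences (>= 2).
#' @param weights per-sequence activity weights (e.g. fold changes).
#' @param highlight significance threshold on raw one-sided p (default
#'   0.001).
#' @return an `activity_logo`: list of L x 4 matrices `p_more`, `p_less`,
#'   `score` (signed -log10 of the smaller p; positive = more active),
#'   `defined`, `significant`.
#' @export
activity_logo <- function(sequences, weights, highlight = 1e-3) {
  n <- length(sequences)
  stopifnot(n == length(weights), n >= 2L)
  mat <- seq_char_matrix(sequences)
  L <- ncol(mat)
  ranks <- rank(weights)
  tt <- table(weights)
  tie_term <- sum(tt^3 - tt)
  dims <- list(seq_len(L), DNA_BASES)
  p_more <- p_less <- matrix(NA_real_, L, 4L, dimnames = dims)
  for (i in seq_len(L)) {
    for (b in seq_along(DNA_BASES)) {
      ps <- mw_onesided(ranks, mat[, i] == DNA_BASES[b], tie_term, n)
      p_more[i, b] <- ps[1]
      p_less[i, b] <- ps[2]
    }
  }
  defined <- !is.na(p_more)
  score <- matrix(0, L, 4L, dimnames = dims)
  score[defined] <- ifelse(p_more[defined] <= p_less[defined],
                           -log10(pmax(p_more[defined], 1e-300)),
                           log10(pmax(p_less[defined], 1e-300)))
  significant <- defined & (pmin(p_more, p_less) < highlight)
  structure(list(p_more = p_more, p_less = p_less, score = score,
                 defined = defined, significant = significant,
                 highlight = highlight),
            class = "activity_logo")
}

#' Two-group positional test
#'
#' Compares a per-variant scalar between two groups with either the
#' Wilcoxon rank-sum test or Welch's t-test (both conventions are used for
#' different displays of such screens).
#'
#' @param values named numeric vector (names = variant keys) or plain
#'   vector indexed by the groups.
#' @param groupA,groupB keys (or indices) of the two groups; nonempty.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return two-sided p-value.
#' @export
positional_group_test <- function(values, groupA, groupB,
                                  method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  a <- values[groupA]
  b <- values[groupB]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (method == "t") {
    if (length(a) < 2L || length(b) < 2L) {
      stop("t-test needs >= 2 values per group", call. = FALSE)
    }
    stats::t.test(a, b)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
}

#' Read a TRANSFAC-like count matrix
#'
#' Parses the classic block layout: numbered rows with four count columns
#' (A C G T order), between `P0`/`PO` header and `XX`/`//` terminators.
#'
#' @param path file path.
#' @return a `pwm` object (counts; see [pwm()]).
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  name <- sub("^ID\\s+", "", grep("^ID\\s", lines, value = TRUE)[1])
  if (is.na(name)) name <- basename(path)
  rows <- grep("^[0-9]+\\s", lines, value = TRUE)
  if (length(rows) == 0L) stop("no matrix rows found", call. = FALSE)
  counts <- do.call(rbind, lapply(rows, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:5])
  }))
  colnames(counts) <- DNA_BASES
  pwm(counts, name = name)
}

#' Construct a position weight matrix
#'
#' @param counts positions x ACGT count (or probability) matrix.
#' @param name motif label.
#' @param pseudocount added to every count before normalisation.
#' @return a `pwm`: list with `name`, `counts` and `prob` (rows sum to 1).
#' @export
pwm <- function(counts, name = "motif", pseudocount = 1) {
  stopifnot(ncol(counts) == 4L)
  colnames(counts) <- DNA_BASES
  prob <- sweep(counts + pseudocount, 1L, rowSums(counts + pseudocount), "/")
  structure(list(name = name, counts = counts, prob = prob,
                 pseudocount = pseudocount), class = "pwm")
}

#' Build a PWM from a sequence set
#'
#' @param sequences equal-length sequences.
#' @inheritParams pwm
#' @return a `pwm`.
#' @export
pwm_from_sequences <- function(sequences, name = "motif", pseudocount = 1) {
  m <- consensus_motif(sequences)
  pwm(m$pfm * m$n, name = name, pseudocount = pseudocount)
}

#' Read an order-m Markov background model from TSV
#'
#' Columns: `context` (length-m string, empty for order 0), `base`,
#' `prob`.  Probabilities must sum to 1 within each context.
#'
#' @param path TSV path.
#' @return a `markov_background`: list with `order` and `prob` lookup.
#' @export
read_markov_background <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(context = "character"))
  stopifnot(all(c("context", "base", "prob") %in% names(df)))
  ord <- unique(nchar(df$context))
  if (length(ord) != 1L) stop("inconsistent context lengths", call. = FALSE)
  sums <- tapply(df$prob, df$context, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("background probabilities must sum to 1 per context", call. = FALSE)
  }
  prob <- stats::setNames(df$prob, paste0(df$context, df$base))
  structure(list(order = ord, prob = prob), class = "markov_background")
}

# log background probability of each base of `chars`, order-m chain with
# uniform fallback for the first m bases.
background_logp <- function(chars, background) {
  n <- length(chars)
  if (is.null(background)) return(rep(log(0.25), n))
  m <- background$order
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= m) {
      out[i] <- log(0.25)
      next
    }
    context <- if (m == 0L) "" else
      paste(chars[(i - m):(i - 1)], collapse = "")
    pr <- background$prob[paste0(context, chars[i])]
    # unseen context: fall back to uniform (documented behaviour)
    out[i] <- if (is.na(pr)) log(0.25) else log(pr)
  }
  out
}

#' Motif weight: best log-odds PWM match
#'
#' Scans every offset on both strands and returns the maximum of
#' sum_i log( p_motif(b_i | i) / p_background(b_i) ).  Background defaults
#' to uniform order 0.
#'
#' @param sequence single DNA string, length >= motif width.
#' @param pwm a [pwm()].
#' @param background optional [read_markov_background()] model.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return maximum log-odds weight (natural log).
#' @export
pwm_score <- function(sequence, pwm, background = NULL, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  assert_dna(sequence, extra = character(0))
  w <- nrow(pwm$prob)
  strands <- if (both_strands) c(sequence, revcomp(sequence)) else sequence
  best <- -Inf
  for (s in strands) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(chars)
    if (L < w) stop("sequence shorter than motif", call. = FALSE)
    bg <- background_logp(chars, background)
    idx <- match(chars, DNA_BASES)
    lp <- log(pwm$prob)
    for (o in 0:(L - w)) {
      sc <- sum(lp[cbind(seq_len(w), idx[o + seq_len(w)])]) -
        sum(bg[o + seq_len(w)])
      if (sc > best) best <- sc
    }
  }
  best
}
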