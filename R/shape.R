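# Pentamer-table DNA shape prediction, profile clustering and group
# comparison.
#
# Shape features are looked up per 5-mer window: minor groove width (MGW, in
# Angstrom) and propeller twist (ProT, degrees) describe the window's centre
# base; roll and helix twist (degrees) describe the two steps adjacent to
# the centre and are averaged where two overlapping windows cover the same
# step.  The two terminal positions on each side are undefined.

SHAPE_BASE_FEATURES <- c("MGW", "ProT")
SHAPE_STEP_FEATURES <- c("Roll", "HelT")

all_pentamers <- function() {
  g <- do.call(expand.grid, c(rep(list(DNA_BASES), 5L),
                              list(KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE)))
  sort(do.call(paste0, g))
}

#' Read a pentamer shape table
#'
#' TSV columns: `pentamer`, `MGW`, `ProT`, `Roll1`, `Roll2`, `HelT1`,
#' `HelT2` (step features for the step before/after the centre base).
#'
#' @param path TSV path.
#' @param partial allow a table that does not cover all 1024 pentamers.
#' @return a `pentamer_table`: data.frame keyed by pentamer, with
#'   `provenance` and `partial` attributes.
#' @export
read_pentamer_table <- function(path, partial = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("pentamer", "MGW", "ProT", "Roll1", "Roll2", "HelT1", "HelT2")
  if (!all(needed %in% names(df))) {
    stop(sprintf("pentamer table must have columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (!partial && nrow(df) < 1024L) {
    stop("table is partial; pass partial = TRUE to allow", call. = FALSE)
  }
  rownames(df) <- df$pentamer
  attr(df, "provenance") <- path
  attr(df, "partial") <- partial
  class(df) <- c("pentamer_table", "data.frame")
  df
}

#' Synthetic pentamer shape tables for testing
#'
#' Not derived from any experimental or simulation source: these fixtures
#' exist so the shape machinery is testable without the published lookup
#' table (which users supply for real analyses).  `"constant"` maps every
#' pentamer to fixed values; `"symmetric"` draws random values constrained
#' to strand symmetry (value(p) = value(revcomp(p)) for base features, and
#' the step features of p mirror those of revcomp(p)), the physical
#' convention for double-helical shape.
#'
#' @param kind `"constant"` or `"symmetric"`.
#' @param seed RNG seed for the symmetric table.
#' @return a `pentamer_table`.
#' @export
synthetic_pentamer_table <- function(kind = c("constant", "symmetric"),
                                     seed = 1L) {
  kind <- match.arg(kind)
  p <- all_pentamers()
  if (kind == "constant") {
    df <- data.frame(pentamer = p, MGW = 5.0, ProT = -7.0,
                     Roll1 = 1.0, Roll2 = 1.0, HelT1 = 34.0, HelT2 = 34.0,
                     stringsAsFactors = FALSE)
  } else {
    set.seed(seed)
    df <- data.frame(pentamer = p,
                     MGW = stats::runif(1024L, 3.5, 6.5),
                     ProT = stats::runif(1024L, -15, 0),
                     Roll1 = stats::runif(1024L, -5, 8),
                     Roll2 = stats::runif(1024L, -5, 8),
                     HelT1 = stats::runif(1024L, 30, 38),
                     HelT2 = stats::runif(1024L, 30, 38),
                     stringsAsFactors = FALSE)
    rc <- revcomp(p)
    first <- p < rc  # canonical member of each reverse-complement pair
    for (i in which(!first)) {
      j <- match(rc[i], p)
      df$MGW[i] <- df$MGW[j]
      df$ProT[i] <- df$ProT[j]
      df$Roll1[i] <- df$Roll2[j]
      df$Roll2[i] <- df$Roll1[j]
      df$HelT1[i] <- df$HelT2[j]
      df$HelT2[i] <- df$HelT1[j]
    }
  }
  rownames(df) <- df$pentamer
  attr(df, "provenance") <- paste0("synthetic-", kind)
  attr(df, "partial") <- FALSE
  class(df) <- c("pentamer_table", "data.frame")
  df
}

#' Predict a shape profile for one sequence
#'
#' @param sequence DNA string over ACGT, length >= 5.
#' @param table a `pentamer_table`.
#' @param feature one of `"MGW"`, `"ProT"` (per base, NA at the two
#'   terminal positions each side) or `"Roll"`, `"HelT"` (per step,
#'   length L-1, NA at the terminal step on each side; interior steps
#'   covered by two windows are averaged).
#' @return numeric profile vector.
#' @export
predict_shape <- function(sequence, table,
                          feature = c("MGW", "ProT", "Roll", "HelT")) {
  feature <- match.arg(feature)
  assert_dna(sequence, extra = character(0))
  L <- nchar(sequence)
  if (L < 5L) stop("sequence must be at least 5 bp", call. = FALSE)
  centers <- 3:(L - 2)
  pent <- substring(sequence, centers - 2L, centers + 2L)
  miss <- !pent %in% rownames(table)
  if (any(miss)) {
    stop(sprintf("pentamer(s) not in table: %s",
                 paste(unique(pent[miss]), collapse = ",")), call. = FALSE)
  }
  if (feature %in% SHAPE_BASE_FEATURES) {
    out <- rep(NA_real_, L)
    out[centers] <- table[pent, feature]
    out
  } else {
    # step j sits between bases j and j+1; window centred at c contributes
    # its "1" value to step c-1 and its "2" value to step c
    v1 <- table[pent, paste0(feature, "1")]
    v2 <- table[pent, paste0(feature, "2")]
    acc <- num <- rep(0, L - 1L)
    acc[centers - 1L] <- acc[centers - 1L] + v1
    num[centers - 1L] <- num[centers - 1L] + 1
    acc[centers] <- acc[centers] + v2
    num[centers] <- num[centers] + 1
    out <- ifelse(num > 0, acc / num, NA_real_)
    out
  }
}

#' Shape profiles for a set of sequences
#'
#' @param sequences equal-length DNA strings.
#' @param table a `pentamer_table`.
#' @param feature shape feature (see [predict_shape()]).
#' @param drop_na drop all-NA terminal columns (default TRUE).
#' @return numeric matrix, sequences x positions; column names are the
#'   1-based positions in the input sequences (or steps for step features).
#' @export
shape_matrix <- function(sequences, table, feature = "MGW", drop_na = TRUE) {
  prof <- t(vapply(sequences, predict_shape, table = table,
                   feature = feature,
                   FUN.VALUE = numeric(
                     nchar(sequences[1]) -
                       (feature %in% SHAPE_STEP_FEATURES)),
                   USE.NAMES = FALSE))
  rownames(prof) <- sequences
  colnames(prof) <- seq_len(ncol(prof))
  if (drop_na) prof <- prof[, colSums(is.na(prof)) == 0, drop = FALSE]
  prof
}

#' K-means clustering of shape profiles
#'
#' Best-of-restarts Lloyd clustering on raw feature values (Euclidean;
#' profiles within a run share units).  `n_init` is the single restart
#' parameter exposed here.
#'
#' @param profiles numeric matrix (variants x positions), no missing
#'   values.
#' @param k number of clusters (default 4).
#' @param n_init random restarts (default 100).
#' @param seed RNG seed.
#' @return a `stats::kmeans` object.
#' @export
kmeans_shape <- function(profiles, k = 4L, n_init = 100L, seed = 1L) {
  if (any(is.na(profiles))) stop("profiles contain missing values",
                                 call. = FALSE)
  if (k > nrow(profiles)) stop("k exceeds the number of profiles",
                               call. = FALSE)
  set.seed(seed)
  stats::kmeans(profiles, centers = k, nstart = n_init, iter.max = 50L)
}

#' Per-position shape comparison between two groups
#'
#' @param profiles numeric matrix (variants x positions).
#' @param groupA,groupB row indices or names; both of size >= 2.
#' @param adjust apply BH across positions (default FALSE: per-position
#'   reporting).
#' @return data.frame with position, p (two-sided Wilcoxon rank-sum),
#'   median difference (A - B) and its sign; undefined (NA) positions are
#'   skipped and flagged.
#' @export
shape_group_comparison <- function(profiles, groupA, groupB,
                                   adjust = FALSE) {
  a <- profiles[groupA, , drop = FALSE]
  b <- profiles[groupB, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("both groups need >= 2 members", call. = FALSE)
  }
  out <- data.frame(position = colnames(profiles),
                    p = NA_real_, median_diff = NA_real_,
                    skipped = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(profiles))) {
    va <- a[, j]; vb <- b[, j]
    if (anyNA(va) || anyNA(vb)) {
      out$skipped[j] <- TRUE
      next
    }
    out$p[j] <- suppressWarnings(stats::wilcox.test(va, vb)$p.value)
    out$median_diff[j] <- stats::median(va) - stats::median(vb)
  }
  if (adjust) {
    out$p_adj <- NA_real_
    ok <- !is.na(out$p)
    out$p_adj[ok] <- bh_adjust(out$p[ok])
  }
  out
}
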