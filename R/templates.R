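# Oligo template parsing and variant-library enumeration.
#
# A designed reporter oligo carries a fixed backbone with degenerate (N)
# positions inside a candidate-enhancer insert.  The insert is located between
# two constant anchor subsequences (the cloning-homology / adapter context),
# and a variant is identified by the bases observed at the N positions only.

#' Parse a designed oligo into a template
#'
#' Locates the candidate-enhancer insert between two constant anchors and
#' records the degenerate (N) positions.  Lowercase bases in the printed
#' oligo are fixed positions; the sequence is uppercase-normalised.
#'
#' @param oligo_sequence single DNA string over A/C/G/T/N (case-insensitive).
#' @param insert_anchors character vector of length 2: the constant
#'   subsequences immediately 5' and 3' of the insert.  Each must occur
#'   exactly once.
#' @param name template label.
#' @param position_labels optional named integer vector mapping biological
#'   position labels (e.g. flank position "6") to 1-based offsets within the
#'   insert.  Interpretation data only; never used in computation.
#' @return an `oligo_template`: list with `name`, `full_sequence`,
#'   `insert_start`, `insert_end` (1-based, closed), `insert` (the insert
#'   sequence with N at degenerate positions), `variable_positions`
#'   (1-based offsets within the insert) and `position_labels`.
#' @examples
#' tpl <- gbs_templates()$cgt
#' length(tpl$variable_positions)  # 5
#' @export
parse_template <- function(oligo_sequence, insert_anchors, name = "template",
                           position_labels = NULL) {
  stopifnot(is.character(oligo_sequence), length(oligo_sequence) == 1L,
            length(insert_anchors) == 2L)
  seq <- toupper(oligo_sequence)
  assert_dna(seq, what = sprintf("oligo '%s'", name))
  anchors <- toupper(insert_anchors)
  hits <- lapply(anchors, function(a) gregexpr(a, seq, fixed = TRUE)[[1]])
  n_hits <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h),
                   integer(1))
  if (any(n_hits != 1L)) {
    stop(sprintf("anchor(s) %s must occur exactly once (found %s times)",
                 paste(sQuote(anchors[n_hits != 1L]), collapse = ", "),
                 paste(n_hits[n_hits != 1L], collapse = ", ")), call. = FALSE)
  }
  insert_start <- hits[[1]][1] + nchar(anchors[1])
  insert_end <- hits[[2]][1] - 1L
  if (insert_end < insert_start) {
    stop("region between anchors is empty", call. = FALSE)
  }
  insert <- substr(seq, insert_start, insert_end)
  variable_positions <- which(strsplit(insert, "", fixed = TRUE)[[1]] == "N")
  structure(
    list(name = name,
         full_sequence = seq,
         insert_start = insert_start,
         insert_end = insert_end,
         insert = insert,
         variable_positions = variable_positions,
         position_labels = position_labels),
    class = "oligo_template")
}

#' @export
print.oligo_template <- function(x, ...) {
  cat(sprintf("oligo_template '%s': %d bp oligo, insert %d-%d (%d bp), %d degenerate position(s)\n",
              x$name, nchar(x$full_sequence), x$insert_start, x$insert_end,
              nchar(x$insert), length(x$variable_positions)))
  invisible(x)
}

# Constant anchor context shared by all inserts of the reporter design:
# cloning homology upstream, sequencing-adapter context downstream.
INSERT_ANCHOR_5P <- "ACACTCTTTCCCTACACGACGCTCT"
INSERT_ANCHOR_3P <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' Built-in synthetic GBS library templates
#'
#' The three designed oligos assayed in the screens: two flank libraries
#' (a fixed 15 bp GR binding sequence, Cgt or Sgk variant, followed by five
#' degenerate flanking positions) and the half-site library (a fixed GR
#' half site plus the first spacer base, followed by eight degenerate
#' positions spanning the rest of the spacer and the second half site).
#'
#' @return named list of [parse_template()] objects: `cgt`, `sgk`, `halfsite`.
#' @export
gbs_templates <- function() {
  cgt <- paste0(
    "TAGAGCATGCACCGGACACTCTTTCCCTACACGACGCTCTTCCGATCTCAGCGCAAGAACAttt",
    "TGTACGNNNNNCTAGATCGGAAGAGCACACGTCTGAACTCCAGTCACTCGACGAATTCGGCC")
  sgk <- paste0(
    "TAGAGCATGCACCGGACACTCTTTCCCTACACGACGCTCTTCCGATCTCAGCGCAAGAACAttt",
    "TGTCCGNNNNNCTAGATCGGAAGAGCACACGTCTGAACTCCAGTCACTCGACGAATTCGGCC")
  halfsite <- paste0(
    "TAGAGCATGCACCGGACACTCTTTCCCTACACGACGCTCTTCCGATCTCAGCGAAAGAACAt",
    "NNNNNNNNCGTCGCTAGATCGGAAGAGCACACGTCTGAACTCCAGTCACTCGACGAATTCGGCC")
  anchors <- c(INSERT_ANCHOR_5P, INSERT_ANCHOR_3P)
  # Biological numbering is an interpretation (the screens' position labels
  # have no stated origin); flank positions 6-12 run 5' to 3' from the last
  # fixed half-site base, half-site labels place the two variable spacer
  # bases at -1/0 and the downstream half site at 1-6.
  flank_labels <- stats::setNames(31:35, as.character(8:12))
  hs_labels <- stats::setNames(23:30, c("-1", "0", as.character(1:6)))
  list(
    cgt = parse_template(cgt, anchors, "cgt_flank", flank_labels),
    sgk = parse_template(sgk, anchors, "sgk_flank", flank_labels),
    halfsite = parse_template(halfsite, anchors, "halfsite", hs_labels))
}

#' Enumerate the full variant space of a template
#'
#' @param template an [parse_template()] object.
#' @param max_positions guard against combinatorial blow-up (default 12).
#' @return a `variant_library`: list with `template` and `keys`, the
#'   lexicographically ordered vector of all 4^k concatenations of bases at
#'   the degenerate positions.
#' @export
enumerate_variants <- function(template, max_positions = 12L) {
  stopifnot(inherits(template, "oligo_template"))
  k <- length(template$variable_positions)
  if (k > max_positions) {
    stop(sprintf("template has %d degenerate positions; capacity limit is %d",
                 k, max_positions), call. = FALSE)
  }
  keys <- if (k == 0L) {
    ""
  } else {
    grid <- do.call(expand.grid,
                    c(rep(list(DNA_BASES), k),
                      list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    sort(do.call(paste0, grid))
  }
  structure(list(template = template, keys = keys), class = "variant_library")
}

#' @export
print.variant_library <- function(x, ...) {
  cat(sprintf("variant_library on '%s': %d variant(s) over %d position(s)\n",
              x$template$name, length(x$keys),
              length(x$template$variable_positions)))
  invisible(x)
}

#' Reconstruct full insert sequences from variant keys
#'
#' @param template an `oligo_template`.
#' @param keys character vector of variant keys (bases at the degenerate
#'   positions, in order).
#' @return character vector of full insert sequences.
#' @export
variant_insert <- function(template, keys) {
  stopifnot(inherits(template, "oligo_template"))
  vp <- template$variable_positions
  k <- length(vp)
  if (k == 0L) return(rep(template$insert, length(keys)))
  if (any(nchar(keys) != k)) {
    stop(sprintf("keys must have %d characters", k), call. = FALSE)
  }
  assert_dna(keys, extra = character(0), what = "variant keys")
  chars <- strsplit(template$insert, "", fixed = TRUE)[[1]]
  key_mat <- seq_char_matrix(keys)
  out_mat <- matrix(chars, nrow = length(keys), ncol = length(chars),
                    byrow = TRUE)
  out_mat[, vp] <- key_mat
  collapse_rows(out_mat)
}

#' Extract variant keys from full insert sequences
#'
#' Inverse of [variant_insert()]: pulls the bases at the degenerate positions.
#' Does not check fixed positions.
#'
#' @param template an `oligo_template`.
#' @param inserts character vector of full insert sequences.
#' @return character vector of keys.
#' @export
insert_key <- function(template, inserts) {
  vp <- template$variable_positions
  mat <- seq_char_matrix(inserts)
  apply(mat[, vp, drop = FALSE], 1L, paste, collapse = "")
}

#' Select variants matching an IUPAC pattern over the insert
#'
#' @param library a `variant_library`.
#' @param pattern IUPAC string of the same length as the insert
#'   (`N`/`n` = any base).
#' @return character vector: the subset of `library$keys` whose full insert
#'   matches the pattern position-by-position.
#' @export
match_pattern <- function(library, pattern) {
  stopifnot(inherits(library, "variant_library"))
  tpl <- library$template
  pattern <- toupper(pattern)
  if (nchar(pattern) != nchar(tpl$insert)) {
    stop(sprintf("pattern length %d != insert length %d",
                 nchar(pattern), nchar(tpl$insert)), call. = FALSE)
  }
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- !pat %in% names(IUPAC_SETS)
  if (any(bad)) {
    stop(sprintf("invalid IUPAC code(s): %s",
                 paste(unique(pat[bad]), collapse = ",")), call. = FALSE)
  }
  fixed_pos <- setdiff(seq_along(pat), tpl$variable_positions)
  tpl_chars <- strsplit(tpl$insert, "", fixed = TRUE)[[1]]
  fixed_ok <- all(vapply(fixed_pos, function(i) {
    tpl_chars[i] %in% IUPAC_SETS[[pat[i]]]
  }, logical(1)))
  if (!fixed_ok) return(character(0))
  keep <- rep(TRUE, length(library$keys))
  key_mat <- seq_char_matrix(library$keys)
  for (j in seq_along(tpl$variable_positions)) {
    i <- tpl$variable_positions[j]
    keep <- keep & key_mat[, j] %in% IUPAC_SETS[[pat[i]]]
  }
  library$keys[keep]
}

#' Group half-site variants by their spacer bases
#'
#' Selects library variants matching a consensus-constrained pattern and
#' groups them by the bases at given key positions (by default the first
#' two, the variable spacer positions of the half-site design).
#'
#' @param library a `variant_library`.
#' @param pattern IUPAC pattern over the insert (see [match_pattern()]).
#' @param group_key_positions indices into the key to group by.
#' @return named list: spacer variant -> matching keys.
#' @export
spacer_groups <- function(library, pattern, group_key_positions = c(1L, 2L)) {
  keys <- match_pattern(library, pattern)
  if (length(keys) == 0L) return(list())
  grp <- apply(seq_char_matrix(keys)[, group_key_positions, drop = FALSE],
               1L, paste, collapse = "")
  split(keys, grp)
}

#' Read a template specification from YAML
#'
#' Expected fields: `name`, `oligo`, `anchor_5p`, `anchor_3p`, and optionally
#' `position_labels` (map label -> 1-based insert offset).
#'
#' @param path YAML file path.
#' @return an `oligo_template`.
#' @export
read_template_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  for (f in c("name", "oligo", "anchor_5p", "anchor_3p")) {
    if (is.null(spec[[f]])) stop(sprintf("template YAML missing '%s'", f),
                                 call. = FALSE)
  }
  labels <- if (!is.null(spec$position_labels)) {
    unlist(spec$position_labels)
  }
  parse_template(spec$oligo, c(spec$anchor_5p, spec$anchor_3p),
                 name = spec$name, position_labels = labels)
}

#' Export a variant library as TSV (key, full insert)
#'
#' @param library a `variant_library`.
#' @param path output file.
#' @export
write_library_tsv <- function(library, path) {
  df <- data.frame(key = library$keys,
                   insert = variant_insert(library$template, library$keys),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
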