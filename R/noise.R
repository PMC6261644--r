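# Expression mean and noise (CV^2) from two-channel single-cell
# fluorescence tables.
#
# Per cell the reporter is normalised by the co-transfected control channel
# (GFP / mCherry), which removes extrinsic noise shared by both channels;
# the population statistics are the mean ratio and CV^2 = variance / mean^2
# with the unbiased (n - 1) variance.

#' Gate fluorescence events
#'
#' Retains events positive in both channels (GFP > and mCherry > their
#' thresholds).  Thresholds are user inputs, as gates are in practice.
#'
#' @param flow data.frame with columns `GFP` and `mCherry` (a
#'   `flow_table`).
#' @param gfp_threshold,mcherry_threshold nonnegative gates.
#' @return gated data.frame with a `retained_fraction` attribute; warns if
#'   empty.
#' @export
gate_events <- function(flow, gfp_threshold = 0, mcherry_threshold = 0) {
  stopifnot(gfp_threshold >= 0, mcherry_threshold >= 0,
            all(c("GFP", "mCherry") %in% names(flow)))
  keep <- flow$GFP > gfp_threshold & flow$mCherry > mcherry_threshold
  out <- flow[keep, , drop = FALSE]
  attr(out, "retained_fraction") <-
    if (nrow(flow)) nrow(out) / nrow(flow) else NA_real_
  if (nrow(out) == 0L) warning("gating retained no events", call. = FALSE)
  out
}

#' Mean and CV^2 of the per-cell reporter ratio
#'
#' @param gated gated `flow_table` (grouping columns `construct`,
#'   `condition`, `replicate` are honoured if present).
#' @param min_cells refuse groups below this size (default 100).
#' @param ratio_mode `"per_cell"` (default: r_i = GFP_i / mCherry_i) or
#'   `"population"` (GFP_i divided by the population-mean mCherry) — the
#'   alternative reading of ratio normalisation, available behind this
#'   flag.
#' @return data.frame with construct, condition, replicate, n, mean, cv2.
#' @export
noise_summary <- function(gated, min_cells = 100L,
                          ratio_mode = c("per_cell", "population")) {
  ratio_mode <- match.arg(ratio_mode)
  for (col in c("construct", "condition", "replicate")) {
    if (!col %in% names(gated)) gated[[col]] <- "all"
  }
  groups <- split(gated,
                  interaction(gated$construct, gated$condition,
                              gated$replicate, drop = TRUE))
  out <- lapply(groups, function(g) {
    n <- nrow(g)
    if (n < min_cells) {
      stop(sprintf("group has %d cells; minimum is %d", n, min_cells),
           call. = FALSE)
    }
    if (any(g$mCherry == 0)) {
      stop("mCherry = 0 after gating; check gates", call. = FALSE)
    }
    r <- switch(ratio_mode,
                per_cell = g$GFP / g$mCherry,
                population = g$GFP / mean(g$mCherry))
    m <- mean(r)
    data.frame(construct = g$construct[1], condition = g$condition[1],
               replicate = g$replicate[1], n = n, mean = m,
               cv2 = stats::var(r) / m^2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate noise summaries across replicates
#'
#' @param summaries [noise_summary()] rows from several replicates.
#' @return per construct/condition: across-replicate mean and SD of both
#'   the mean ratio and CV^2; SD is NA (flagged) for single replicates.
#' @export
aggregate_replicates <- function(summaries) {
  groups <- split(summaries,
                  interaction(summaries$construct, summaries$condition,
                              drop = TRUE))
  out <- lapply(groups, function(g) {
    single <- nrow(g) < 2L
    data.frame(construct = g$construct[1], condition = g$condition[1],
               n_replicates = nrow(g),
               mean_expr = mean(g$mean),
               sd_expr = if (single) NA_real_ else stats::sd(g$mean),
               mean_cv2 = mean(g$cv2),
               sd_cv2 = if (single) NA_real_ else stats::sd(g$cv2),
               sd_undefined = single, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a flow-cytometry event table
#'
#' CSV with at least `event_id`, `GFP`, `mCherry`; `construct`,
#' `condition`, `replicate` are carried through when present.
#'
#' @param path CSV path.
#' @return a `flow_table` data.frame.
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("GFP", "mCherry") %in% names(df))) {
    stop("flow CSV needs GFP and mCherry columns", call. = FALSE)
  }
  if (any(!is.finite(df$GFP)) || any(!is.finite(df$mCherry))) {
    stop("non-finite intensities", call. = FALSE)
  }
  df
}

#' Suggest gate thresholds from a no-reporter control table
#'
#' @param control `flow_table` measured without the reporter.
#' @param quantile_level upper quantile of the control used as gate
#'   (default 0.99).
#' @return named vector: gfp_threshold, mcherry_threshold.
#' @export
suggest_gates <- function(control, quantile_level = 0.99) {
  c(gfp_threshold = unname(stats::quantile(control$GFP, quantile_level)),
    mcherry_threshold = unname(stats::quantile(control$mCherry,
                                               quantile_level)))
}
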