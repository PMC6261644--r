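# Synthetic screens, reads and single-cell fluorescence populations.
#
# The generator reproduces the statistical structure the downstream analysis
# assumes: a lognormally skewed plasmid pool with dropout; negative-binomial
# replicate counts (variance mu + alpha*mu^2) under a hormone vs vehicle
# design with planted log2 effects; paired reads carrying the exact insert;
# and two-channel fluorescence populations whose reporter channel follows the
# steady-state gamma approximation of a two-state (bursting) promoter.

#' Configuration for a simulated reporter screen
#'
#' Defaults mirror the study design: three hormone (dex) and three vehicle
#' replicates, lognormal plasmid-pool abundances, NB counts with dispersion
#' `alpha`, and planted log2 effects on a subset of variants (15% enhancing
#' at +1, 10% blunting at -1).
#'
#' @param library a `variant_library`.
#' @param n_replicates replicates per condition.
#' @param depth expected total read count per sample.
#' @param meanlog,sdlog lognormal parameters of the plasmid-pool abundances.
#' @param dropout_fraction fraction of variants absent from the pool.
#' @param size_factor_mult per-sample depth multipliers (length
#'   `2 * n_replicates`, vehicle samples first), default all 1.
#' @param alpha NB dispersion: scalar, per-variant vector, or function of the
#'   expected base mean.
#' @param f_enh,f_blunt fractions of variants with planted positive/negative
#'   effects (fractions must sum to at most 1).
#' @param beta_enh,beta_blunt planted log2 fold changes (dex vs vehicle).
#' @param seed integer RNG seed (mandatory; no hidden global state).
#' @return a `screen_sim_config` list.
#' @export
screen_sim_config <- function(library, n_replicates = 3L, depth = 5e6,
                              meanlog = 0, sdlog = 0.5,
                              dropout_fraction = 0, size_factor_mult = NULL,
                              alpha = 0.05, f_enh = 0.15, f_blunt = 0.10,
                              beta_enh = 1, beta_blunt = -1, seed = 1L) {
  stopifnot(inherits(library, "variant_library"),
            n_replicates >= 1L, depth > 0,
            dropout_fraction >= 0, dropout_fraction < 1,
            f_enh + f_blunt <= 1, f_enh >= 0, f_blunt >= 0)
  if (length(library$keys) == 0L) stop("empty library", call. = FALSE)
  if (is.numeric(alpha) && any(alpha < 0)) stop("alpha must be >= 0",
                                                call. = FALSE)
  if (is.null(size_factor_mult)) size_factor_mult <- rep(1, 2L * n_replicates)
  stopifnot(length(size_factor_mult) == 2L * n_replicates,
            all(size_factor_mult > 0))
  structure(list(library = library, n_replicates = as.integer(n_replicates),
                 depth = depth, meanlog = meanlog, sdlog = sdlog,
                 dropout_fraction = dropout_fraction,
                 size_factor_mult = size_factor_mult, alpha = alpha,
                 f_enh = f_enh, f_blunt = f_blunt,
                 beta_enh = beta_enh, beta_blunt = beta_blunt,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate a variant screen
#'
#' Vehicle counts are NB with mean `s_j * q_v`; dex counts with mean
#' `s_j * q_v * 2^beta_v`.  `q_v` is proportional to the lognormal pool
#' abundance times depth; dropout variants are zero everywhere.
#'
#' @param config a [screen_sim_config()].
#' @return a `simulated_screen`: list with `counts` (integer matrix,
#'   variants x samples), `samples` (sample sheet data.frame with columns
#'   sample_id, condition, replicate) and `truth` (data.frame with per-variant
#'   true log2 effect `beta`, `class` and `dropout` flag).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  keys <- config$library$keys
  n_var <- length(keys)
  n_rep <- config$n_replicates

  dropout <- rep(FALSE, n_var)
  n_drop <- round(config$dropout_fraction * n_var)
  if (n_drop > 0) dropout[sample.int(n_var, n_drop)] <- TRUE

  abundance <- stats::rlnorm(n_var, config$meanlog, config$sdlog)
  abundance[dropout] <- 0
  prop <- abundance / sum(abundance)

  beta <- rep(0, n_var)
  cls <- rep("neutral", n_var)
  eligible <- which(!dropout)
  n_enh <- round(config$f_enh * length(eligible))
  n_blunt <- round(config$f_blunt * length(eligible))
  pick <- sample(eligible, n_enh + n_blunt)
  if (n_enh > 0) {
    beta[pick[seq_len(n_enh)]] <- config$beta_enh
    cls[pick[seq_len(n_enh)]] <- "enhancing"
  }
  if (n_blunt > 0) {
    idx <- pick[n_enh + seq_len(n_blunt)]
    beta[idx] <- config$beta_blunt
    cls[idx] <- "blunting"
  }

  conditions <- rep(c("vehicle", "dex"), each = n_rep)
  sample_id <- paste0(conditions, "_", rep(seq_len(n_rep), times = 2L))
  sf <- config$size_factor_mult

  q <- prop * config$depth
  alpha_v <- if (is.function(config$alpha)) config$alpha(q) else
    rep_len(config$alpha, n_var)

  counts <- matrix(0L, n_var, 2L * n_rep,
                   dimnames = list(keys, sample_id))
  for (j in seq_along(sample_id)) {
    mu <- sf[j] * q * if (conditions[j] == "dex") 2^beta else 1
    pos <- mu > 0
    size <- ifelse(alpha_v[pos] <= 0, 1e8, 1 / alpha_v[pos])
    counts[pos, j] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
  }
  storage.mode(counts) <- "integer"

  truth <- data.frame(key = keys, beta = beta, class = cls,
                      dropout = dropout, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, condition = conditions,
                        replicate = rep(seq_len(n_rep), times = 2L),
                        stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, truth = truth,
                 config = config),
            class = "simulated_screen")
}

#' Write simulated paired-end reads for a screen
#'
#' Emits `counts[v, s]` read pairs per variant and sample.  Read 1 is the
#' realised oligo sequence (template with the variant's bases substituted),
#' read 2 its reverse complement, each subject to independent per-base
#' substitution errors at `error_rate`.  Files are written as
#' `<sample_id>_R1.fastq` / `<sample_id>_R2.fastq` with constant Phred+33
#' qualities.
#'
#' @param screen a [simulate_screen()] result.
#' @param template the `oligo_template` the screen's library was built on.
#' @param dir output directory (created if needed).
#' @param error_rate per-base substitution probability in [0, 0.5).
#' @param seed integer RNG seed.
#' @return data.frame with sample_id, fastq1, fastq2, n_reads.
#' @export
simulate_reads <- function(screen, template = screen$config$library$template,
                           dir, error_rate = 0, seed = 1L) {
  stopifnot(inherits(screen, "simulated_screen"),
            error_rate >= 0, error_rate < 0.5)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  keys <- rownames(screen$counts)
  oligo <- template$full_sequence
  vp_oligo <- template$insert_start - 1L + template$variable_positions
  oligo_chars <- strsplit(oligo, "", fixed = TRUE)[[1]]

  out <- data.frame(sample_id = screen$samples$sample_id,
                    fastq1 = NA_character_, fastq2 = NA_character_,
                    n_reads = 0L, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(screen$counts))) {
    sid <- colnames(screen$counts)[j]
    n_per <- screen$counts[, j]
    total <- sum(n_per)
    f1 <- file.path(dir, paste0(sid, "_R1.fastq"))
    f2 <- file.path(dir, paste0(sid, "_R2.fastq"))
    if (total == 0L) {
      file.create(f1); file.create(f2)
    } else {
      key_rep <- rep(keys[n_per > 0], n_per[n_per > 0])
      key_mat <- seq_char_matrix(key_rep)
      read_mat <- matrix(oligo_chars, nrow = length(key_rep),
                         ncol = length(oligo_chars), byrow = TRUE)
      read_mat[, vp_oligo] <- key_mat
      r1 <- apply_seq_errors(read_mat, error_rate)
      r2 <- revcomp(apply_seq_errors(read_mat, error_rate))
      ord <- sample.int(length(r1))  # shuffle so counting is order-tested
      ids <- sprintf("%s_read%06d", sid, seq_along(r1))
      write_fastq(ids, r1[ord], f1)
      write_fastq(ids, r2[ord], f2)
    }
    out$fastq1[j] <- f1; out$fastq2[j] <- f2; out$n_reads[j] <- total
  }
  out
}

# Apply iid per-base substitution errors to a character matrix of reads and
# collapse rows to strings.
apply_seq_errors <- function(read_mat, error_rate) {
  if (error_rate > 0) {
    n <- length(read_mat)
    hit <- which(stats::runif(n) < error_rate)
    if (length(hit)) {
      # replace with one of the three other bases, uniformly
      cur <- read_mat[hit]
      repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
      read_mat[hit] <- repl
    }
  }
  collapse_rows(read_mat)
}

write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}

#' Configuration for a simulated fluorescence population
#'
#' The reporter channel follows the steady-state gamma approximation of a
#' two-state promoter: GFP ~ Gamma(shape = burst frequency a, scale = burst
#' size b), so mean = a*b and CV^2 = 1/a.  An optional extrinsic per-cell
#' factor scales both channels (so ratio normalisation removes it), and
#' multiplicative lognormal measurement noise is applied per channel.
#'
#' @param n_cells number of cells.
#' @param burst_freq bursts per protein lifetime (gamma shape), > 0.
#' @param burst_size mean burst size (gamma scale), > 0.
#' @param mcherry_mean,mcherry_cv mean and CV of the normalisation channel.
#' @param extrinsic_cv CV of the shared per-cell extrinsic factor.
#' @param noise_cv CV of the per-channel multiplicative measurement noise.
#' @param seed integer RNG seed.
#' @return a `flow_sim_config` list.
#' @export
flow_sim_config <- function(n_cells = 1000L, burst_freq = 4, burst_size = 250,
                            mcherry_mean = 1000, mcherry_cv = 0.25,
                            extrinsic_cv = 0, noise_cv = 0, seed = 1L) {
  stopifnot(n_cells >= 1L, burst_freq > 0, burst_size > 0,
            mcherry_mean > 0, mcherry_cv >= 0,
            extrinsic_cv >= 0, noise_cv >= 0)
  structure(list(n_cells = as.integer(n_cells), burst_freq = burst_freq,
                 burst_size = burst_size, mcherry_mean = mcherry_mean,
                 mcherry_cv = mcherry_cv, extrinsic_cv = extrinsic_cv,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "flow_sim_config")
}

# Lognormal draws with a given mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a two-channel fluorescence population
#'
#' @param config a [flow_sim_config()].
#' @param construct,condition,replicate labels stamped on the table.
#' @return data.frame (`flow_table` layout) with columns event_id, GFP,
#'   mCherry, construct, condition, replicate.
#' @export
simulate_flow_population <- function(config, construct = "construct",
                                     condition = "dex", replicate = 1L) {
  stopifnot(inherits(config, "flow_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  # per-cell extrinsic state (transfection dose, size, machinery) scales
  # both channels, so ratio normalisation removes it; the mCherry CV is one
  # more extrinsic source, likewise shared
  extrinsic <- rlnorm_mean_cv(n, 1, config$extrinsic_cv) *
    rlnorm_mean_cv(n, 1, config$mcherry_cv)
  burst <- stats::rgamma(n, shape = config$burst_freq,
                         scale = config$burst_size)
  gfp <- burst * extrinsic * rlnorm_mean_cv(n, 1, config$noise_cv)
  mch <- config$mcherry_mean * extrinsic *
    rlnorm_mean_cv(n, 1, config$noise_cv)
  data.frame(event_id = seq_len(n), GFP = gfp, mCherry = mch,
             construct = construct, condition = condition,
             replicate = replicate, stringsAsFactors = FALSE)
}
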