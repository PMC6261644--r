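# Activity classification from sequence or shape: positional likelihood-
# ratio models (mono- and dinucleotide), binary-coded and shape random
# forests, and a pooled 10-fold cross-validated ROC harness.

#' Mononucleotide likelihood-ratio classifier
#'
#' Estimates per-class position frequency matrices with an additive
#' pseudocount; the score of a sequence is the summed per-position
#' log-likelihood ratio (class 1 over class 2).
#'
#' @param sequences equal-length training sequences.
#' @param labels binary labels (coerced to factor; the *second* level is
#'   class 1, the positive class).
#' @param pseudocount Laplace smoothing constant (default 1).
#' @return scorer function: character vector of sequences -> numeric
#'   log-likelihood-ratio scores (higher = more class-1-like).
#' @export
fit_mononuc_lr <- function(sequences, labels, pseudocount = 1) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) == 0L)) {
    stop("need two nonempty classes", call. = FALSE)
  }
  pos <- levels(labels)[2L]
  f1 <- class_freqs(sequences[labels == pos], pseudocount)
  f0 <- class_freqs(sequences[labels != pos], pseudocount)
  lr <- log(f1) - log(f0)
  function(x) {
    mat <- seq_char_matrix(x)
    idx <- match(mat, DNA_BASES)
    dim(idx) <- dim(mat)
    vapply(seq_len(nrow(mat)), function(r) {
      sum(lr[cbind(seq_len(ncol(mat)), idx[r, ])])
    }, numeric(1))
  }
}

class_freqs <- function(sequences, pseudocount) {
  mat <- seq_char_matrix(sequences)
  counts <- t(apply(mat, 2L, function(col) {
    tabulate(factor(col, levels = DNA_BASES), nbins = 4L)
  }))
  counts <- counts + pseudocount
  sweep(counts, 1L, rowSums(counts), "/")
}

#' Dinucleotide likelihood-ratio classifier
#'
#' As [fit_mononuc_lr()] but over adjacent-pair frequencies at every
#' position pair (i, i+1); the score sums the log ratios over all L-1
#' pairs.
#'
#' @inheritParams fit_mononuc_lr
#' @return scorer function.
#' @export
fit_dinuc_lr <- function(sequences, labels, pseudocount = 1) {
  if (unique(nchar(sequences))[1] < 2L) {
    stop("sequences must have length >= 2 for dinucleotides", call. = FALSE)
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) == 0L)) {
    stop("need two nonempty classes", call. = FALSE)
  }
  pos <- levels(labels)[2L]
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  f1 <- dinuc_freqs(sequences[labels == pos], dinucs, pseudocount)
  f0 <- dinuc_freqs(sequences[labels != pos], dinucs, pseudocount)
  lr <- log(f1) - log(f0)
  function(x) {
    mat <- seq_char_matrix(x)
    L <- ncol(mat)
    di <- matrix(paste0(mat[, -L, drop = FALSE], mat[, -1L, drop = FALSE]),
                 nrow = nrow(mat))
    idx <- match(di, dinucs)
    dim(idx) <- dim(di)
    vapply(seq_len(nrow(mat)), function(r) {
      sum(lr[cbind(seq_len(L - 1L), idx[r, ])])
    }, numeric(1))
  }
}

dinuc_freqs <- function(sequences, dinucs, pseudocount) {
  mat <- seq_char_matrix(sequences)
  L <- ncol(mat)
  di <- matrix(paste0(mat[, -L, drop = FALSE], mat[, -1L, drop = FALSE]),
               nrow = nrow(mat))
  counts <- t(apply(di, 2L, function(col) {
    tabulate(factor(col, levels = dinucs), nbins = 16L)
  }))
  counts <- counts + pseudocount
  sweep(counts, 1L, rowSums(counts), "/")
}

#' Two-bit binary encoding of sequences
#'
#' A = 00, C = 01, G = 10, T = 11; each sequence becomes a row of 2L binary
#' features (the coding that makes nucleotide data digestible for a random
#' forest).
#'
#' @param sequences equal-length sequences over ACGT.
#' @return n x 2L matrix with entries in {0, 1}.
#' @export
encode_binary <- function(sequences) {
  assert_dna(sequences, extra = character(0))
  mat <- seq_char_matrix(sequences)
  code <- rbind(A = c(0, 0), C = c(0, 1), G = c(1, 0), T = c(1, 1))
  out <- matrix(0, nrow(mat), 2L * ncol(mat))
  for (i in seq_len(ncol(mat))) {
    out[, 2L * i - 1L] <- code[mat[, i], 1L]
    out[, 2L * i] <- code[mat[, i], 2L]
  }
  colnames(out) <- paste0("pos", rep(seq_len(ncol(mat)), each = 2L),
                          c("_hi", "_lo"))
  out
}

#' Decode two-bit encoded sequences
#'
#' @param mat matrix from [encode_binary()].
#' @return character vector of sequences.
#' @export
decode_binary <- function(mat) {
  L <- ncol(mat) / 2L
  apply(mat, 1L, function(r) {
    hi <- r[seq(1L, 2L * L, by = 2L)]
    lo <- r[seq(2L, 2L * L, by = 2L)]
    paste(DNA_BASES[2L * hi + lo + 1L], collapse = "")
  })
}

#' Random-forest scorer on a numeric feature matrix
#'
#' 100-tree forest (by default); the score is the class-1 vote fraction.
#'
#' @param features numeric matrix.
#' @param labels binary labels (second factor level = positive class).
#' @param n_trees trees (default 100).
#' @param seed RNG seed.
#' @return scorer function: feature matrix -> positive-class vote
#'   fraction.
#' @export
fit_rf_scorer <- function(features, labels, n_trees = 100L, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  pos <- levels(labels)[2L]
  set.seed(seed)
  rf <- randomForest::randomForest(x = features, y = labels,
                                   ntree = n_trees)
  function(x) {
    unname(stats::predict(rf, x, type = "prob")[, pos])
  }
}

#' ROC curve and AUC from pooled scores
#'
#' Points run from (0,0) to (1,1) over decreasing score thresholds; AUC is
#' the trapezoidal area, which (with tied scores handled by averaging)
#' equals the Mann-Whitney concordance probability.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (second factor level = positive).
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.factor(labels)
  pos <- levels(labels)[2L]
  y <- labels == pos
  if (!any(y) || all(y)) stop("need both classes", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!y & scores >= t), numeric(1))
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc)
}

#' Cross-validated ROC
#'
#' Stratified fold assignment; each fold is scored by a model trained on
#' the rest and the held-out scores are pooled into a single ROC.
#'
#' @param fit_fun function(items, labels) -> scorer function (e.g. a
#'   wrapped [fit_mononuc_lr()] or [fit_rf_scorer()]).
#' @param items character vector of sequences or a numeric feature matrix.
#' @param labels binary labels.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param stratified keep class proportions per fold (default TRUE; under
#'   FALSE a fold missing a class is an error).
#' @return a `roc_result`: list with `fpr`, `tpr`, `auc`, `scores`,
#'   `fold`, `folds`, `seed`, `stratified`.
#' @export
cross_validate_roc <- function(fit_fun, items, labels, folds = 10L,
                               seed = 1L, stratified = TRUE) {
  labels <- as.factor(labels)
  n <- if (is.matrix(items)) nrow(items) else length(items)
  stopifnot(n == length(labels), n >= folds)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("need both classes", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold <- sample(rep_len(seq_len(folds), n))
  }
  scores <- numeric(n)
  take <- function(obj, i) if (is.matrix(obj)) obj[i, , drop = FALSE]
                           else obj[i]
  for (f in seq_len(folds)) {
    test <- fold == f
    train_lab <- droplevels(labels[!test])
    if (nlevels(train_lab) != 2L) {
      stop(sprintf("fold %d training set is missing a class", f),
           call. = FALSE)
    }
    scorer <- fit_fun(take(items, !test), labels[!test])
    scores[test] <- scorer(take(items, test))
  }
  roc <- roc_curve(scores, labels)
  structure(list(fpr = roc$fpr, tpr = roc$tpr, auc = roc$auc,
                 scores = scores, fold = fold, folds = folds, seed = seed,
                 stratified = stratified),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d-fold CV, pooled scores, seed %d)\n",
              x$auc, x$folds, x$seed))
  invisible(x)
}
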