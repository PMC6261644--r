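random_seqs <- function(n, L) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * L, TRUE), n, L),
        1, paste, collapse = "")
}

test_that("likelihood-ratio classifiers separate what they should", {
  set.seed(41)
  # identical class distributions: chance-level AUC
  seqs <- random_seqs(400, 8)
  labs <- factor(rep(c("lo", "hi"), each = 200), levels = c("lo", "hi"))
  cv <- cross_validate_roc(function(it, lb) fit_mononuc_lr(it, lb),
                           seqs, labs, seed = 1)
  expect_gt(cv$auc, 0.4)
  expect_lt(cv$auc, 0.6)
  # perfectly separable single position
  sep <- seqs
  substr(sep[labs == "hi"], 3, 3) <- "A"
  substr(sep[labs == "lo"], 3, 3) <- "C"
  cv_sep <- cross_validate_roc(function(it, lb) fit_mononuc_lr(it, lb),
                               sep, labs, seed = 1)
  expect_equal(cv_sep$auc, 1)
  # pseudocount keeps scores finite even for one-sequence classes
  scorer <- fit_mononuc_lr(c("ACGT", "ACGT", "TTTT"),
                           factor(c("a", "a", "b")), pseudocount = 1)
  expect_true(all(is.finite(scorer(c("GGGG", "ACGT")))))
  expect_error(fit_mononuc_lr("ACGT", factor("a")), "two nonempty")
})

test_that("dinucleotide model captures correlation the mononuc one misses", {
  set.seed(42)
  n <- 500
  # class 1: perfectly correlated adjacent pair; class 0: independent.
  # Marginals identical (uniform) at both positions.
  pair1 <- sample(c("A", "C", "G", "T"), n, TRUE)
  class1 <- paste0(pair1, pair1)
  class0 <- paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                   sample(c("A", "C", "G", "T"), n, TRUE))
  seqs <- c(class1, class0)
  labs <- factor(rep(c("corr", "indep"), each = n),
                 levels = c("indep", "corr"))
  auc_mono <- cross_validate_roc(function(it, lb) fit_mononuc_lr(it, lb),
                                 seqs, labs, seed = 2)$auc
  auc_di <- cross_validate_roc(function(it, lb) fit_dinuc_lr(it, lb),
                               seqs, labs, seed = 2)$auc
  expect_gt(auc_di, auc_mono + 0.1)
  expect_error(fit_dinuc_lr(c("A", "C"), factor(c("a", "b"))), "length >= 2")
})

test_that("dinucleotide model does not beat mononuc on independent data", {
  deltas <- numeric(5)
  for (s in 1:5) {
    set.seed(500 + s)
    seqs <- random_seqs(600, 6)
    # position-independent signal at position 2
    labs <- factor(ifelse(substr(seqs, 2, 2) %in% c("A", "G"), "hi", "lo"),
                   levels = c("lo", "hi"))
    auc_mono <- cross_validate_roc(function(it, lb) fit_mononuc_lr(it, lb),
                                   seqs, labs, seed = s)$auc
    auc_di <- cross_validate_roc(function(it, lb) fit_dinuc_lr(it, lb),
                                 seqs, labs, seed = s)$auc
    deltas[s] <- auc_di - auc_mono
  }
  expect_lt(mean(deltas), 0.05)
})

test_that("binary coding follows the two-bit convention and inverts", {
  expect_equal(unname(encode_binary("A")[1, ]), c(0, 0))
  expect_equal(unname(encode_binary("T")[1, ]), c(1, 1))
  expect_equal(unname(encode_binary("ACGT")[1, ]),
               c(0, 0, 0, 1, 1, 0, 1, 1))
  set.seed(43)
  s <- random_seqs(20, 9)
  expect_equal(unname(decode_binary(encode_binary(s))), s)
  expect_error(encode_binary("ACGN"), "characters")
})

test_that("random forests score features reproducibly", {
  set.seed(44)
  n <- 200
  labs <- factor(rep(c("neg", "pos"), each = n / 2),
                 levels = c("neg", "pos"))
  perfect <- cbind(signal = as.numeric(labs == "pos"),
                   noise = rnorm(n))
  cv <- cross_validate_roc(function(it, lb) fit_rf_scorer(it, lb, seed = 7),
                           perfect, labs, seed = 3)
  expect_equal(cv$auc, 1)
  # pure noise: chance level over repeats
  aucs <- vapply(1:5, function(s) {
    set.seed(600 + s)
    x <- matrix(rnorm(n * 6), n, 6)
    cross_validate_roc(function(it, lb) fit_rf_scorer(it, lb, seed = s),
                       x, labs, seed = s)$auc
  }, numeric(1))
  expect_true(all(aucs > 0.35 & aucs < 0.65))
  # same data + seeds: identical ROC
  x <- matrix(rnorm(n * 4), n, 4)
  r1 <- cross_validate_roc(function(it, lb) fit_rf_scorer(it, lb, seed = 9),
                           x, labs, seed = 5)
  r2 <- cross_validate_roc(function(it, lb) fit_rf_scorer(it, lb, seed = 9),
                           x, labs, seed = 5)
  expect_identical(r1$scores, r2$scores)
  expect_error(fit_rf_scorer(x[1:5, ], factor(rep("a", 5))), "both classes")
})

test_that("pooled-ROC AUC equals Mann-Whitney concordance", {
  set.seed(45)
  labels <- factor(sample(c("n", "p"), 30, TRUE), levels = c("n", "p"))
  scores <- rnorm(30) + as.numeric(labels == "p")
  scores[c(3, 7)] <- scores[c(5, 9)]  # inject ties
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, auc_bruteforce(scores, labels))
  # degenerate cases
  expect_equal(roc_curve(rep(1, 30), labels)$auc, 0.5)
  sep <- ifelse(labels == "p", 2, 1)
  expect_equal(roc_curve(sep, labels)$auc, 1)
  # curve is monotone from (0,0) to (1,1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(tail(roc$fpr, 1), tail(roc$tpr, 1)), c(1, 1))
  # symmetry identities
  expect_equal(roc_curve(-scores, labels)$auc, 1 - roc$auc)
  flipped <- factor(ifelse(labels == "p", "n", "p"), levels = c("n", "p"))
  expect_equal(roc_curve(scores, flipped)$auc, 1 - roc$auc)
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                             direction = "<", quiet = TRUE))
  expect_equal(roc$auc, as.numeric(ref))
})

test_that("cross-validation stratifies folds and pools held-out scores", {
  set.seed(46)
  labs <- factor(c(rep("a", 40), rep("b", 20)), levels = c("a", "b"))
  seqs <- random_seqs(60, 5)
  cv <- cross_validate_roc(function(it, lb) fit_mononuc_lr(it, lb),
                           seqs, labs, folds = 10, seed = 4)
  per_fold <- table(cv$fold, labs)
  expect_true(all(per_fold[, "b"] == 2))  # stratification balances classes
  expect_length(cv$scores, 60L)
  expect_error(cross_validate_roc(function(it, lb) fit_mononuc_lr(it, lb),
                                  seqs[1:5], labs[1:5], folds = 10),
               "n >= folds|folds")
})

test_that("shape-based forest matches sequence forest on shape-ruled data", {
  tab <- synthetic_pentamer_table("symmetric", seed = 51)
  lib <- enumerate_variants(fix_templates$cgt)
  set.seed(52)
  keys <- sample(lib$keys, 300)
  ctx <- variant_insert(lib$template, keys)
  profiles <- shape_matrix(ctx, tab, "MGW")
  score <- rowMeans(profiles[, intersect(as.character(29:35),
                                         colnames(profiles))])
  activity <- -score + rnorm(300, 0, 0.05)
  labs <- factor(ifelse(activity > median(activity), "hi", "lo"),
                 levels = c("lo", "hi"))
  auc_shape <- cross_validate_roc(
    function(it, lb) fit_rf_scorer(it, lb, seed = 1), profiles, labs,
    seed = 6)$auc
  auc_seq <- cross_validate_roc(
    function(it, lb) fit_rf_scorer(it, lb, seed = 1), encode_binary(keys),
    labs, seed = 6)$auc
  expect_gte(auc_shape, auc_seq - 0.02)
})
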