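test_that("ranking orders by fold change with lexicographic tie-break", {
  res <- data.frame(key = c("CA", "AA", "BA", "AC"),
                    log2FoldChange = c(1, 2, 1, 2))
  rk <- rank_variants(res)
  expect_equal(rk$ranked$key, c("AA", "AC", "BA", "CA"))
  # permutation of the input
  expect_setequal(rk$ranked$key, res$key)
  expect_equal(dim(rk$chart), c(4L, 2L))
})

test_that("top ranks are enriched for planted enhancers", {
  lib <- small_flank_library(256L)
  cfg <- screen_sim_config(lib, depth = 1e6, alpha = 0.05, seed = 17)
  out <- run_flank_screen(cfg)
  rk <- rank_variants(out$results, cfg$library)
  truth <- out$screen$truth
  top <- rk$ranked$key[1:40]
  n_enh_top <- sum(truth$class[match(top, truth$key)] == "enhancing")
  p <- phyper(n_enh_top - 1, sum(truth$class == "enhancing"),
              sum(truth$class != "enhancing"), 40, lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("consensus motifs report frequencies and information content", {
  m <- consensus_motif(rep("ACGT", 10))
  expect_equal(unname(m$ic), rep(2, 4))
  expect_equal(unname(m$pfm[1, "A"]), 1)
  expect_true(all(abs(rowSums(m$pfm) - 1) < 1e-9))
  single <- consensus_motif("GATTACA")
  expect_equal(unname(single$ic), rep(2, 7))
  expect_error(consensus_motif(c("AC", "ACG")), "equal length")
  # uniform random sequences carry almost no information
  set.seed(2)
  rnd <- apply(matrix(sample(c("A", "C", "G", "T"), 4 * 1e4, TRUE), ncol = 4),
               1, paste, collapse = "")
  expect_lt(mean(consensus_motif(rnd)$ic), 0.05)
})

test_that("activity logo pinpoints a constructed single-position signal", {
  lib <- enumerate_variants(fix_templates$cgt)
  seqs <- lib$keys
  w <- as.numeric(substr(seqs, 1, 1) == "T")
  logo <- activity_logo(seqs, w)
  expect_equal(which(logo$p_more == min(logo$p_more, na.rm = TRUE)),
               which(rownames(logo$p_more) == "1") +
                 nrow(logo$p_more) * (match("T", colnames(logo$p_more)) - 1))
  expect_true(logo$significant[1, "T"])
  expect_equal(logo$score[1, "T"], -log10(logo$p_more[1, "T"]))
})

test_that("logo rank tests agree with the reference implementation", {
  set.seed(5)
  lib <- small_flank_library(200L)
  seqs <- lib$keys
  w <- rnorm(200) + as.numeric(substr(seqs, 3, 3) == "G")
  logo <- activity_logo(seqs, w)
  for (pos in c(1L, 3L)) {
    for (b in c("A", "G")) {
      g <- substr(seqs, pos, pos) == b
      ref_more <- wilcox.test(w[g], w[!g], alternative = "greater",
                              exact = FALSE)$p.value
      ref_less <- wilcox.test(w[g], w[!g], alternative = "less",
                              exact = FALSE)$p.value
      expect_equal(logo$p_more[pos, b], ref_more, tolerance = 1e-10)
      expect_equal(logo$p_less[pos, b], ref_less, tolerance = 1e-10)
    }
  }
  # complementary one-sided p-values overlap near 1
  expect_true(all(logo$p_more + logo$p_less >= 1, na.rm = TRUE))
})

test_that("logo p-values are calibrated under weight independence", {
  lib <- enumerate_variants(fix_templates$cgt)
  seqs <- lib$keys
  n_sig <- 0L
  n_cells <- 0L
  pvals <- numeric(0)
  for (s in 1:20) {
    set.seed(1000 + s)
    w <- rnorm(length(seqs))
    logo <- activity_logo(seqs, w)
    n_sig <- n_sig + sum(logo$significant)
    n_cells <- n_cells + sum(logo$defined)
    pvals <- c(pvals, logo$p_more[1, ])
  }
  # expected fraction of cells significant in either direction ~ 2e-3
  expect_lte(n_sig / n_cells, 2e-3 + 3 * sqrt(2e-3 / n_cells))
  # one-sided p-values approximately uniform
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("tiny inputs give bounded, unhighlighted logos", {
  # two sequences: every defined p-value is >= 1/3, nothing highlighted
  logo <- activity_logo(c("AC", "TG", "AC", "TG")[1:2], c(1, 2),
                        highlight = 1e-3)
  defined_p <- pmin(logo$p_more, logo$p_less)[logo$defined]
  expect_true(all(defined_p >= 1 / 3))
  expect_false(any(logo$significant))
  # constant column: undefined cells flagged, no test
  logo2 <- activity_logo(c("AC", "AG", "AT", "AA"), c(1, 2, 3, 4))
  expect_true(all(is.na(logo2$p_more[1, ])))
  expect_false(any(logo2$defined[1, ]))
})

test_that("positional group tests dispatch to both conventions", {
  set.seed(4)
  x <- setNames(c(rnorm(50), rnorm(50, 2)), paste0("v", 1:100))
  a <- paste0("v", 1:50)
  b <- paste0("v", 51:100)
  expect_lt(positional_group_test(x, a, b, method = "wilcoxon"), 1e-6)
  expect_lt(positional_group_test(x, a, b, method = "t"), 1e-6)
  same <- setNames(rep(c(1, 2), 10), paste0("v", 1:20))
  expect_equal(positional_group_test(same, paste0("v", 1:10),
                                     paste0("v", 11:20)), 1)
  expect_error(positional_group_test(x, a, character(0)), "nonempty")
  expect_error(positional_group_test(x, a[1], b[1], method = "t"), ">= 2")
})

test_that("PWM scoring reproduces hand-computed log-odds", {
  # 2-position toy motif: counts A:3,C:1 / G:3,T:1, pseudocount 1
  p <- pwm(rbind(c(3, 1, 0, 0), c(0, 0, 3, 1)), pseudocount = 1)
  expect_equal(pwm_score("AG", p, both_strands = FALSE),
               2 * log((4 / 8) / (1 / 4)))
  # uniform motif, uniform background: weight 0 everywhere
  u <- pwm(matrix(1, 3, 4), pseudocount = 0)
  expect_equal(pwm_score("ACGTT", u), 0)
  # the consensus sequence maximises the score
  set.seed(6)
  cm <- pwm(matrix(rpois(20, 5) + 1, 5, 4), pseudocount = 1)
  consensus <- paste(c("A", "C", "G", "T")[apply(cm$prob, 1, which.max)],
                     collapse = "")
  others <- replicate(50, paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                                collapse = ""))
  sc <- vapply(others, pwm_score, numeric(1), pwm = cm,
               both_strands = FALSE)
  expect_true(all(pwm_score(consensus, cm, both_strands = FALSE) >= sc))
  expect_error(pwm_score("ACX", p), "characters")
})

test_that("sequences sampled from a PWM outscore background sequences", {
  set.seed(8)
  counts <- rbind(c(80, 5, 10, 5), c(5, 80, 5, 10), c(10, 5, 80, 5),
                  c(5, 10, 5, 80), c(80, 5, 10, 5))
  motif <- pwm(counts)
  sample_from <- function(prob) {
    apply(prob, 1, function(p) sample(c("A", "C", "G", "T"), 1, prob = p))
  }
  planted <- replicate(200, paste(sample_from(motif$prob), collapse = ""))
  background <- replicate(200, paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                                     collapse = ""))
  sp <- vapply(planted, pwm_score, numeric(1), pwm = motif)
  sb <- vapply(background, pwm_score, numeric(1), pwm = motif)
  expect_gt(median(sp) - median(sb), 0)
  expect_lt(wilcox.test(sp, sb, alternative = "greater")$p.value, 1e-6)
})

test_that("TRANSFAC matrices and Markov backgrounds load from text", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("ID toy_motif", "P0  A  C  G  T",
               "01  8  1  1  0", "02  0  0  9  1", "XX", "//"), tf)
  m <- read_transfac(tf)
  expect_equal(m$name, "toy_motif")
  expect_equal(unname(m$counts[1, ]), c(8, 1, 1, 0))
  bg <- tempfile(fileext = ".tsv")
  writeLines(c("context\tbase\tprob",
               paste("", c("A", "C", "G", "T"),
                     c(0.4, 0.1, 0.1, 0.4), sep = "\t")), bg)
  model <- read_markov_background(bg)
  expect_equal(model$order, 0L)
  # AT-rich background penalises AT-rich matches relative to uniform
  sc_uniform <- pwm_score("AT", pwm(rbind(c(9, 0, 0, 1), c(1, 0, 0, 9))),
                          both_strands = FALSE)
  sc_bg <- pwm_score("AT", pwm(rbind(c(9, 0, 0, 1), c(1, 0, 0, 9))),
                     background = model, both_strands = FALSE)
  expect_lt(sc_bg, sc_uniform)
})
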