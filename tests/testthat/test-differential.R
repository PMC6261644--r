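test_that("size factors follow the median-of-ratios construction", {
  m <- matrix(c(10L, 20L, 40L,
                10L, 20L, 40L,
                10L, 20L, 40L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("v", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), c(0.5, 1, 2) / exp(mean(log(c(0.5, 1, 2)))))
  # identical columns: all factors 1
  eqm <- matrix(5L, 4, 3, dimnames = list(paste0("v", 1:4), paste0("s", 1:3)))
  expect_equal(unname(size_factors(eqm)), rep(1, 3))
  # doubling one column doubles its factor relative to the others
  dbl <- eqm
  dbl[, 2] <- 10L
  sf <- size_factors(dbl)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # single sample
  expect_equal(unname(size_factors(eqm[, 1, drop = FALSE])), 1)
  # no variant covered everywhere
  z <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(z), "pseudo-reference")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
})

test_that("dispersion estimates recover the generating model", {
  lib <- small_flank_library(400L)
  # Poisson data: shrunken dispersions collapse toward zero
  cfg <- screen_sim_config(lib, depth = 4e5, sdlog = 0.2, alpha = 1e-9,
                           f_enh = 0, f_blunt = 0, seed = 61)
  scr <- simulate_screen(cfg)
  sf <- size_factors(scr$counts)
  fit <- fit_dispersions(scr$counts, sf, scr$samples$condition)
  expect_lt(median(fit$final), 0.01)
  # constant alpha = 0.2: the trend sits near it at mid-range means
  cfg2 <- screen_sim_config(lib, depth = 4e5, sdlog = 0.2, alpha = 0.2,
                            f_enh = 0, f_blunt = 0, seed = 62)
  scr2 <- simulate_screen(cfg2)
  fit2 <- fit_dispersions(scr2$counts, size_factors(scr2$counts),
                          scr2$samples$condition)
  mid <- fit2$baseMean > quantile(fit2$baseMean, 0.25) &
    fit2$baseMean < quantile(fit2$baseMean, 0.75)
  expect_true(all(fit2$trend[mid] > 0.1 & fit2$trend[mid] < 0.4))
  # constant counts within conditions: raw dispersion at the floor
  const <- matrix(rep(c(50L, 100L), each = 3), 1, 6,
                  dimnames = list("v", paste0("s", 1:6)))
  fitc <- fit_dispersions(rbind(const, const + 1L),
                          rep(1, 6), rep(c("vehicle", "dex"), each = 3))
  expect_lt(fitc$raw[1], 1e-6)
  expect_error(fit_dispersions(const[, c(1, 4), drop = FALSE], rep(1, 2),
                               c("vehicle", "dex")), ">= 2 samples")
})

test_that("Wald estimates agree with the reference NB workflow", {
  skip_if_not_installed("DESeq2")
  lib <- small_flank_library(300L)
  cfg <- screen_sim_config(lib, depth = 1.5e6, alpha = 0.05, seed = 71)
  scr <- simulate_screen(cfg)
  res <- differential_activity(scr$counts, scr$samples)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    scr$counts,
    data.frame(condition = factor(scr$samples$condition,
                                  levels = c("vehicle", "dex"))),
    ~condition)
  dds <- DESeq2::DESeq(dds, fitType = "local", betaPrior = FALSE,
                       quiet = TRUE)
  ref <- DESeq2::results(dds)
  expect_gt(cor(res$log2FoldChange, ref$log2FoldChange), 0.9999)
  expect_lt(max(abs(res$log2FoldChange - ref$log2FoldChange)), 0.01)
  # calls largely agree at the screen's cutoff
  agree <- mean((res$padj < 0.01) == (ref$padj < 0.01), na.rm = TRUE)
  expect_gt(agree, 0.95)
})

test_that("condition swap negates effects and preserves p-values", {
  lib <- small_flank_library(150L)
  cfg <- screen_sim_config(lib, depth = 5e5, alpha = 0.05, seed = 81)
  scr <- simulate_screen(cfg)
  res <- differential_activity(scr$counts, scr$samples)
  swapped <- scr$samples
  swapped$condition <- ifelse(swapped$condition == "dex", "vehicle", "dex")
  res_sw <- differential_activity(scr$counts, swapped)
  expect_equal(res_sw$log2FoldChange, -res$log2FoldChange, tolerance = 1e-6)
  expect_equal(res_sw$pvalue, res$pvalue, tolerance = 1e-6)
  tab <- table(res$class, res_sw$class)
  expect_equal(unname(tab["enhancing", "blunting"]),
               sum(res$class == "enhancing"))
})

test_that("effect estimates are approximately unbiased under the NB model", {
  lib <- small_flank_library(400L)
  cfg <- screen_sim_config(lib, depth = 2e6, alpha = 0.05, sdlog = 0.3,
                           seed = 91)
  scr <- simulate_screen(cfg)
  res <- differential_activity(scr$counts, scr$samples)
  truth <- scr$truth[match(res$key, scr$truth$key), ]
  bias <- mean(res$log2FoldChange - truth$beta)
  expect_lt(abs(bias), 0.05)
})

test_that("zero counts in one condition are flagged with finite estimates", {
  m <- matrix(c(0L, 0L, 0L, 200L, 230L, 210L,
                100L, 110L, 90L, 100L, 95L, 105L,
                80L, 90L, 100L, 85L, 95L, 105L,
                120L, 100L, 110L, 115L, 105L, 95L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("v", 1:4), paste0("s", 1:6)))
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        condition = rep(c("vehicle", "dex"), each = 3),
                        replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  res <- differential_activity(m, samples)
  expect_true(res$zero_condition[1])
  expect_true(is.finite(res$log2FoldChange[1]))
  expect_gt(res$log2FoldChange[1], 5)
})

test_that("classification partitions the tested set and applies cutoffs", {
  res <- data.frame(key = paste0("v", 1:4),
                    log2FoldChange = c(3, 1, -3, 0.5),
                    padj = c(1e-6, 1e-4, 1e-6, 0.5))
  fl <- suppressWarnings(classify_variants(res, mode = "flank"))
  expect_equal(fl$class, c("enhancing", "enhancing", "blunting", "neutral"))
  expect_equal(sum(attr(fl, "class_counts")), nrow(res))
  hs <- suppressWarnings(classify_variants(res, mode = "halfsite"))
  expect_equal(hs$class,
               c("activated", "weak", "repressed", "not_significant"))
  all_null <- transform(res, padj = 1)
  expect_true(all(suppressWarnings(
    classify_variants(all_null, mode = "flank"))$class == "neutral"))
})

test_that("replicate correlations are computed per condition pair", {
  lib <- small_flank_library(100L)
  scr <- simulate_screen(screen_sim_config(lib, depth = 5e5, seed = 15))
  rc <- replicate_correlations(scr$counts, scr$samples)
  expect_equal(nrow(rc), 6L)  # 3 pairs per condition
  expect_true(all(rc$r > 0.7))
})
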