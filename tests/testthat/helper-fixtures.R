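# Shared fixtures, built in code at test time.

# Flank-library template and a small sub-library for fast read-level tests.
fix_templates <- gbs_templates()

small_flank_library <- function(n = 128L) {
  lib <- enumerate_variants(fix_templates$cgt)
  lib$keys <- lib$keys[seq(1L, length(lib$keys), length.out = n)]
  lib
}

# Sub-library closed under single substitutions: keys whose base-index sum
# is 0 mod 4.  Any one-base change at a degenerate position leaves the
# library, so error-rate arithmetic matches the per-base closed form.
parity_flank_library <- function() {
  lib <- enumerate_variants(fix_templates$cgt)
  idx <- vapply(strsplit(lib$keys, ""), function(ch) {
    sum(match(ch, c("A", "C", "G", "T")) - 1L) %% 4L
  }, integer(1))
  lib$keys <- lib$keys[idx == 0L]
  lib
}

# A template with two degenerate positions for exact enumeration checks.
tiny_template <- function() {
  parse_template("AAACCCGGGTTTACGNAGCNTTTGGGCCCAAA", c("CCCGGGTTT", "TTTGGGCCC"),
                 name = "tiny")
}

# Hand-rolled brute-force BH step-up, kept deliberately naive.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Pairwise-concordance AUC (Mann-Whitney identity), brute force.
auc_bruteforce <- function(scores, labels) {
  labels <- as.factor(labels)
  pos <- scores[labels == levels(labels)[2L]]
  neg <- scores[labels != levels(labels)[2L]]
  gr <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}
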