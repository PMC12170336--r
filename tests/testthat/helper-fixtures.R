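# Shared fixture builders for the test suite.

# A tiny in-memory PSM table in the package's standardized layout.
make_psm_fixture <- function() {
  psms <- data.frame(
    peptide = c("ACDKFNGLK", "ACDKFNGLK", "ACDKFNGLK", "WLDNMRK"),
    protein = c("P1", "P1", "P1", "P2"),
    site_position = c(6L, 6L, 6L, 4L),
    composition = c("HexNAc(2)Hex(5)", "HexNAc(2)Hex(5)",
                    "HexNAc(2)Hex(9)", "HexNAc(4)Hex(5)Fuc(1)"),
    glycan_q = c(0.01, 0.02, 0.001, 0.04),
    ms1_intensity = c(5e6, 3e6, 1e6, 2e6),
    spectrum_id = paste0("s", 1:4),
    peptide_start = c(1L, 1L, 1L, 1L),
    channel_01 = c(1, 1, 2, 4),
    channel_02 = c(2, 3, 2, 4),
    stringsAsFactors = FALSE)
  structure(psms, mode = "N", channels = c("01", "02"))
}

# Glycopeptide records spanning several sites for heterogeneity tests.
make_site_records <- function() {
  data.frame(
    protein = c(rep("P1", 5), rep("P2", 3)),
    site_position = c(10L, 10L, 10L, 40L, 40L, 7L, 7L, 7L),
    peptide = c(rep("AAANK", 3), rep("CCCNK", 2), rep("DDDNK", 3)),
    composition = c("HexNAc(2)Hex(5)", "HexNAc(2)Hex(9)", "HexNAc(2)Hex(3)",
                    "HexNAc(2)Hex(5)", "HexNAc(2)Hex(9)",
                    "HexNAc(1)", "HexNAc(2)Hex(5)", "NeuAc(1)HexNAc(2)Hex(5)"),
    ms1_intensity = c(3e6, 1e6, 1e6, 2e6, 2e6, 5e5, 5e5, 1e6),
    stringsAsFactors = FALSE)
}

# Brute-force Kendall tau-b by explicit pair counting (independent oracle).
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx != 0 && dy != 0) {
      if (sign(dx) == sign(dy)) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) { t <- table(v); sum(t * (t - 1) / 2) }
  n1 <- tie_pairs(x); n2 <- tie_pairs(y)
  if (n1 == n0 || n2 == n0) return(NA_real_)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Two-sided Fisher exact p by full hypergeometric enumeration (oracle).
enum_fisher_p <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force Benjamini-Hochberg step-up (oracle).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Best-permutation agreement between cluster labels and planted truth.
perm_matched_accuracy <- function(cluster, truth) {
  ks <- sort(unique(truth))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  best <- 0
  for (p in perms(seq_along(ks))) {
    mapped <- ks[p][match(cluster, seq_along(ks))]
    best <- max(best, mean(mapped == truth))
  }
  best
}
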