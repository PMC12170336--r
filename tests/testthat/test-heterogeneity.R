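test_that("site summaries count distinct glycoforms and bin them", {
  rec <- make_site_records()
  # duplicate a composition at P1 site 10 via a second peptide entry
  rec <- rbind(rec, data.frame(protein = "P1", site_position = 10L,
                               peptide = "OTHERNK",
                               composition = "HexNAc(2)Hex(5)",
                               ms1_intensity = 1e5))
  s <- site_microheterogeneity(rec, mode = "N")
  p1s10 <- s[s$protein == "P1" & s$site_position == 10, ]
  expect_equal(p1s10$n_glycoforms, 3L)
  expect_equal(as.character(p1s10$heterogeneity_bin), "medium")
  expect_equal(p1s10$class_high_mannose, 2L)
  expect_equal(p1s10$class_paucimannose, 1L)

  wide <- data.frame(protein = "PX", site_position = 1L,
                     composition = sprintf("HexNAc(2)Hex(%d)", 1:12))
  expect_equal(as.character(
    site_microheterogeneity(wide)$heterogeneity_bin), "high")
  two <- site_microheterogeneity(make_site_records())
  expect_equal(as.character(
    two$heterogeneity_bin[two$protein == "P2"]), "medium")

  empty <- site_microheterogeneity(make_site_records()[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("fractional intensities normalize per site", {
  rec <- data.frame(protein = "P", site_position = 1L,
                    composition = c("HexNAc(1)", "HexNAc(2)"),
                    ms1_intensity = c(3e6, 1e6))
  fr <- fractional_intensity(rec)
  expect_equal(fr$fractions$fraction, c(0.75, 0.25))
  expect_equal(nrow(fr$top), 0L)  # < 10 glycoforms: no top-fraction entry

  rec10 <- data.frame(protein = "P", site_position = 2L,
                      composition = sprintf("HexNAc(2)Hex(%d)", 1:10),
                      ms1_intensity = rep(7, 10))
  fr10 <- fractional_intensity(rec10)
  expect_equal(fr10$top$top_fraction, 0.1)

  # property: fractions sum to 1 per site on simulated data
  sim <- simulate_glycoproteome(sim_config(seed = 3, n_proteins = 15L))
  rec_sim <- collapse_unique(qc_filter(sim$psms))
  fs <- fractional_intensity(rec_sim)$fractions
  sums <- tapply(fs$fraction, paste(fs$protein, fs$site_position), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  zero <- rec; zero$ms1_intensity <- 0
  expect_true(all(fractional_intensity(zero)$fractions$degenerate))
})

test_that("low/high microheterogeneity labels use the 90th percentile", {
  mk <- function(counts) data.frame(protein = "P",
                                    site_position = seq_along(counts),
                                    n_glycoforms = counts)
  # distribution built so the 90th percentile is exactly 44
  counts <- c(rep(1, 80), rep(44, 11), rep(80, 9))
  lab <- label_low_high(mk(counts))
  expect_equal(attr(lab, "threshold"), 44)
  expect_true(all(lab$ml_label[lab$n_glycoforms == 80] == "high"))
  expect_true(all(lab$ml_label[lab$n_glycoforms == 44] == "unlabeled"))
  expect_true(all(lab$ml_label[lab$n_glycoforms == 1] == "low"))

  expect_warning(all_one <- label_low_high(mk(rep(1, 30))), "degenerate")
  expect_true(all(all_one$ml_label == "low"))
})

test_that("kendall tau-b agrees with brute-force pair counting", {
  set.seed(81)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(0:3, n, replace = TRUE)
    expect_equal(kendall_tau_b(x, y), brute_tau_b(x, y), tolerance = 1e-12)
    xb <- sample(0:1, n, replace = TRUE)
    yb <- sample(0:1, n, replace = TRUE)
    expect_equal(kendall_tau_b(xb, yb), brute_tau_b(xb, yb),
                 tolerance = 1e-12)
  }
  expect_true(is.na(kendall_tau_b(c(1, 1, 1), c(0, 1, 0))))
})

test_that("within-protein profile correlations behave at the extremes", {
  # identical presence vectors -> tau 1 (a third composition elsewhere in
  # the dataset keeps the vectors non-constant over the universe)
  rec <- data.frame(protein = c(rep("P", 4), "Q"),
                    site_position = c(1L, 1L, 2L, 2L, 1L),
                    composition = c("HexNAc(1)", "HexNAc(2)",
                                    "HexNAc(1)", "HexNAc(2)", "HexNAc(3)"))
  expect_equal(site_profile_correlation(rec)$tau, 1)

  # disjoint single-composition sites over a 2-composition universe -> -1
  rec2 <- data.frame(protein = "P", site_position = c(1L, 2L),
                     composition = c("HexNAc(1)", "HexNAc(2)"))
  expect_equal(site_profile_correlation(rec2)$tau, -1)

  # independent random vectors: mean tau within 3 se of 0
  set.seed(91)
  n_prot <- 400; comps <- sprintf("HexNAc(2)Hex(%d)", 1:8)
  rec3 <- do.call(rbind, lapply(1:n_prot, function(i) {
    do.call(rbind, lapply(1:2, function(s) data.frame(
      protein = paste0("P", i), site_position = s,
      composition = sample(comps, sample(2:6, 1)))))
  }))
  taus <- site_profile_correlation(rec3)$tau
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus)), 3 * se + 0.02)
})

test_that("the shuffle null separates planted composition sharing", {
  cfg <- sim_config(seed = 7, n_proteins = 25L, share_prob = 0.8,
                    sites_per_protein_lambda = 2)
  sim <- simulate_glycoproteome(cfg)
  rec <- sim$truth$features
  sn <- shuffle_null(rec, n_perm = 10, seed = 17)
  expect_gt(sn$observed_median, sn$shuffled_median)
  expect_lt(sn$p, 0.01)

  # permutations preserve per-site glycoform counts exactly
  perm <- rec
  set.seed(1)
  perm$composition <- sample(perm$composition)
  n_obs <- table(paste(rec$protein, rec$site_position))
  n_perm <- table(paste(perm$protein, perm$site_position))
  expect_equal(n_obs, n_perm)

  expect_error(shuffle_null(rec, n_perm = 0), "n_perm")
})

test_that("phosphosite proximity is window-inclusive and mode-aware", {
  rec <- data.frame(protein = "P1", site_position = c(100L, 100L),
                    peptide_start = c(40L, 40L),
                    composition = "HexNAc(1)")
  ph <- data.frame(protein = "P1", position = c(105L, 36L))
  expect_true(phospho_proximity(rec, ph, "N")$near_phospho[1])
  expect_false(phospho_proximity(rec, data.frame(protein = "P1",
                                                 position = 106L),
                                 "N")$near_phospho[1])
  expect_true(phospho_proximity(rec, ph, "O")$near_phospho[1])
  expect_false(phospho_proximity(rec, data.frame(protein = "P2",
                                                 position = 100L),
                                 "N")$near_phospho[1])
})

test_that("contingency enrichment matches the hypergeometric oracle", {
  flat <- contingency_enrichment(matrix(10, 2, 2))
  expect_equal(flat$odds_ratio, rep(1, 4))
  expect_equal(flat$log2_odds_ratio, rep(0, 4))
  expect_equal(flat$p, rep(1, 4))

  skew <- contingency_enrichment(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
  cell <- skew[skew$category == "cat1" & skew$group == "grp1", ]
  expect_equal(cell$p, enum_fisher_p(matrix(c(8, 2, 2, 8), 2)),
               tolerance = 1e-9)
  expect_equal(cell$p, 0.023, tolerance = 0.002)
  expect_equal(cell$odds_ratio, 16)

  zero <- contingency_enrichment(matrix(c(5, 0, 5, 5), 2, byrow = TRUE))
  expect_true(all(is.finite(zero$log2_odds_ratio)))  # Haldane correction

  expect_error(contingency_enrichment(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")

  # random tables vs full enumeration
  set.seed(101)
  for (i in 1:30) {
    m <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    got <- contingency_enrichment(m)
    expect_equal(got$p[1], enum_fisher_p(m), tolerance = 1e-9)
  }
})
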