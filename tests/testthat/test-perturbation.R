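make_diff <- function(features, lfc, sig, contrast = "treated_vs_control") {
  data.frame(feature = features, contrast = contrast, log2_fc = lfc,
             p_raw = ifelse(sig, 1e-6, 0.5),
             p_adj = ifelse(sig, 1e-5, 0.6), significant = sig,
             stringsAsFactors = FALSE)
}

test_that("site exposure needs at least two affected glycoforms", {
  site_map <- data.frame(feature = paste0("f", 1:6),
                         protein = c("P1", "P1", "P1", "P2", "P2", "P3"),
                         site_position = c(10L, 10L, 10L, 5L, 5L, 9L))
  diff <- make_diff(paste0("f", 1:6), c(-2, -1.5, -1, -2, 0.1, -2),
                    c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  res <- classify_site_exposure(diff, site_map)
  expect_equal(res$affected[res$protein == "P1"], TRUE)   # 3 significant
  expect_equal(res$affected[res$protein == "P2"], FALSE)  # only 1
  expect_equal(res$n_significant_glycoforms[res$protein == "P2"], 1L)
  expect_equal(res$affected[res$protein == "P3"], FALSE)

  none <- classify_site_exposure(
    make_diff(paste0("f", 1:6), 0, rep(FALSE, 6)), site_map)
  expect_true(all(!none$affected))
  # deterministic function of its input
  expect_identical(classify_site_exposure(diff, site_map), res)
})

test_that("composition exposure counts agree across identical treatments", {
  features <- data.frame(feature = paste0("f", 1:8),
                         composition = rep(c("HexNAc(2)Hex(5)",
                                             "HexNAc(4)Hex(5)Fuc(1)"), 4),
                         protein = rep(c("P1", "P2"), each = 4),
                         site_position = rep(c(1L, 2L), each = 4))
  diff <- make_diff(paste0("f", 1:8), rnorm(8, -1),
                    c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  res <- composition_exposure_counts(diff, diff, features)
  expect_equal(res$count_correlation, 1)
  expect_equal(res$fc_correlation, 1)
  expect_equal(res$counts$n_significant_a, res$counts$n_significant_b)
})

test_that("neural gas converges to the centroid for k = 1", {
  set.seed(121)
  x <- matrix(rnorm(200 * 3), 200, 3)
  fit <- neural_gas(x, k = 1, seed = 9)
  expect_lt(sqrt(sum((fit$prototypes[1, ] - colMeans(x))^2)), 1e-1)
  expect_equal(unique(fit$cluster), 1L)
})

test_that("neural gas recovers separated blobs and is deterministic", {
  set.seed(131)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  truth <- rep(1:3, each = 60)
  x <- centers[truth, ] + matrix(rnorm(360, 0, 1), 180, 2)
  fit <- neural_gas(x, k = 3, seed = 4)
  expect_equal(perm_matched_accuracy(fit$cluster, truth), 1)
  fit2 <- neural_gas(x, k = 3, seed = 4)
  expect_identical(fit$prototypes, fit2$prototypes)
  expect_identical(fit$cluster, fit2$cluster)

  # quantization error non-increasing in k (median over seeds)
  qe <- sapply(1:5, function(k) stats::median(sapply(1:5, function(s)
    neural_gas(x, k, seed = s)$quant_error)))
  expect_true(all(diff(qe) <= 1e-9))

  expect_error(neural_gas(x[c(1, 1), ], k = 3), "distinct")
  expect_error(neural_gas(x, k = 2, epsilon_initial = 1.2), "epsilon")
})

test_that("kinetic clustering recovers planted prototype assignments", {
  sim <- simulate_experiment("time_course", sim_config(seed = 23))
  times <- unique(sim$design$time)
  contrasts <- lapply(times, function(tt)
    c(paste0("treated_", tt), paste0("control_", tt)))
  diff <- differential(sim$glyco, sim$design, contrasts)
  diff$contrast <- sub("_vs_.*$", "", sub("^treated_", "", diff$contrast))
  clu <- cluster_kinetics(diff, k = 4, seed = 3)
  truth <- sim$truth$cluster[clu$membership$feature]
  # regulated features dominate the clustered set; compare on those
  keep <- truth > 0
  expect_gt(mean(keep), 0.9)
  expect_gte(perm_matched_accuracy(clu$membership$cluster[keep],
                                   truth[keep]), 0.9)

  # fucosylated ever-downregulated subset at k = 3
  clu3 <- cluster_kinetics(diff, k = 3, select = "fucosylated_down",
                           classes = sim$truth$classes, seed = 3)
  expect_true(all(sim$truth$classes[clu3$membership$feature] ==
                  "fucosylated"))
  expect_error(cluster_kinetics(diff[diff$feature %in%
                                       diff$feature[1:2], ], k = 4),
               "fewer")
})

test_that("single shared profile collapses to one cluster", {
  prof <- c(-1, -2, -2, -2)
  diff <- do.call(rbind, lapply(1:4, function(t)
    make_diff(paste0("f", 1:10), prof[t], TRUE, contrast = paste0("t", t))))
  clu <- cluster_kinetics(diff, k = 1, seed = 1)
  expect_equal(unname(clu$cluster_means[1, ]), prof)
})
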