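test_that("normalization methods satisfy their calibration contracts", {
  set.seed(31)
  x <- matrix(rlnorm(200, 12, 1), ncol = 4)

  # median scaling: exact scalar multiples become identical columns
  y <- cbind(x[, 1], 3.7 * x[, 1])
  med <- normalize_intensities(y, "median")
  expect_equal(med[, 1], med[, 2], tolerance = 1e-12)

  # quantile: per-column sorted values all equal
  q <- normalize_intensities(x, "quantile")
  s <- apply(q, 2, sort)
  expect_true(all(abs(s - s[, 1]) < 1e-9))

  # vsn-like: medians and MADs equalized, ranks preserved, positivity needed
  v <- normalize_intensities(x, "vsn_like")
  expect_equal(diff(range(apply(v, 2, median))), 0, tolerance = 1e-9)
  expect_equal(diff(range(apply(v, 2, mad))), 0, tolerance = 1e-9)
  expect_equal(order(v[, 1]), order(x[, 1]))
  expect_equal(attr(v, "scale"), "normalized")
  xx <- x; xx[1, 1] <- -1
  expect_error(normalize_intensities(xx, "vsn_like"), "positive")
})

test_that("regression correction removes protein-driven trends", {
  prot <- matrix(rnorm(6, 20, 1), 1, dimnames = list("P1", NULL))
  # glycopeptide tracking the protein exactly (affine): residuals collapse
  g <- matrix(2 * prot[1, ] + 3, 1, dimnames = list("gp1", NULL))
  out <- correct_by_regression(g, prot, "P1")
  expect_equal(as.numeric(out), rep(mean(g), 6), tolerance = 1e-9)

  # constant protein profile: slope-0 fallback returns the input
  flat <- matrix(5, 1, 6, dimnames = list("P1", NULL))
  out2 <- correct_by_regression(g, flat, "P1")
  expect_equal(as.numeric(out2), as.numeric(g))
  expect_true(attr(out2, "zero_variance"))

  # unmatched features pass through flagged
  out3 <- correct_by_regression(g, prot, NA_character_)
  expect_equal(as.numeric(out3), as.numeric(g))
  expect_true(attr(out3, "unmatched"))

  # planted independent effect is recovered at low noise
  set.seed(41)
  n <- 50; s <- 100  # many samples: the fitted slope error becomes negligible
  p <- matrix(rnorm(n * s, 20, 2), n, dimnames = list(paste0("P", 1:n), NULL))
  effect <- matrix(rnorm(n * s, 0, 1), n)
  g2 <- p + effect + matrix(rnorm(n * s, 0, 0.05), n)
  rownames(g2) <- paste0("gp", 1:n)
  corr <- correct_by_regression(g2, p, paste0("P", 1:n))
  cen <- function(m) m - rowMeans(m)
  cors <- sapply(1:n, function(i) cor(cen(corr)[i, ], cen(effect)[i, ]))
  expect_gt(mean(cors), 0.99)
})

test_that("ratio correction matches the printed formula and its invariances", {
  # single-feature fixed point: g = median_g, p = median_p -> median_g
  g <- matrix(c(2e6, 1e6), 2, 1, dimnames = list(c("a", "b"), NULL))
  p <- matrix(c(4e6, 2e6), 2, 1, dimnames = list(c("PA", "PB"), NULL))
  out <- correct_by_ratio(g, p, c("PA", "PB"))
  # hand evaluation: med_g = 1.5e6, med_p = 3e6;
  # a: ((2e6/4e6)/(1.5e6/3e6)) * 1.5e6 = 1.5e6
  expect_equal(unname(out["a", 1]), ((2e6 / 4e6) / (1.5e6 / 3e6)) * 1.5e6)
  expect_equal(unname(out["b", 1]), ((1e6 / 2e6) / (1.5e6 / 3e6)) * 1.5e6)

  # global protein rescaling cancels exactly
  for (c_ in c(0.1, 7, 1000)) {
    out_c <- correct_by_ratio(g, c_ * p, c("PA", "PB"))
    expect_equal(out_c, out, tolerance = 1e-12, ignore_attr = TRUE)
  }

  # zero protein intensity gives a missing cell
  p0 <- p; p0["PA", 1] <- 0
  out0 <- correct_by_ratio(g, p0, c("PA", "PB"))
  expect_true(is.na(out0["a", 1]))
})

test_that("differential analysis applies the significance rule and design", {
  set.seed(51)
  n <- 200
  base <- rnorm(n, 20, 1)
  eff <- c(rep(2, 20), rep(0.5, 20), rep(0, n - 40))
  x <- cbind(matrix(base, n, 3), matrix(base + eff, n, 3)) +
    matrix(rnorm(n * 6, 0, 0.05), n)
  rownames(x) <- paste0("f", 1:n)
  design <- data.frame(condition = rep(c("ctrl", "trt"), each = 3),
                       replicate = rep(1:3, 2))
  res <- differential(x, design, list(c("trt", "ctrl")))
  expect_equal(nrow(res), n)
  expect_true(all(res$p_adj >= res$p_raw))
  # strong spikes called, |lfc| = 0.5 < log2(1.5) never called regardless of p
  expect_true(all(res$significant[1:20]))
  expect_true(all(!res$significant[21:40]))
  expect_true(all(abs(res$log2_fc[1:20] - 2) < 0.2))

  expect_error(differential(x, design, list(c("trt", "absent"))),
               "absent")
})

test_that("moderated statistic approaches the ordinary t at large n", {
  set.seed(61)
  n <- 50; r <- 200
  sds <- runif(n, 0.5, 2)  # heteroscedastic features, as in real data
  x <- matrix(rnorm(n * 2 * r, 10, rep(sds, 2 * r)), n)
  design <- data.frame(condition = rep(c("a", "b"), each = r))
  res <- differential(x, design, list(c("b", "a")))
  t_classic <- apply(x, 1, function(v)
    unname(t.test(v[(r + 1):(2 * r)], v[1:r], var.equal = TRUE)$statistic))
  # invert the reported p back to the |t| scale (residual df = 2r - 2; the
  # small moderated prior df changes the inversion negligibly here)
  t_implied <- qt(res$p_raw / 2, df = 2 * r - 2, lower.tail = FALSE)
  rel <- abs(t_implied - abs(t_classic)) / abs(t_classic)
  expect_lt(median(rel), 0.01)
  expect_lt(max(rel), 0.05)
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(1), 1)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(71)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(benjamini_hochberg(p), brute_bh(p))
    expect_true(all(benjamini_hochberg(p) >= p))
  }
})
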