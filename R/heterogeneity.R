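# Site microheterogeneity, fractional intensities, within-protein
# glycosylation-profile similarity with a permutation null, phosphosite
# proximity and contingency enrichment.

#' Per-site microheterogeneity summary
#'
#' Counts distinct glycan compositions per glycosite, tallies glycan classes,
#' and bins sites as low (1-2 glycoforms), medium (3-10) or high (11 or
#' more).
#'
#' @param records Glycopeptide record data frame with `protein`,
#'   `site_position`, `composition`.
#' @param mode `"N"` or `"O"`: classification hierarchy used for class
#'   tallies.
#' @return Data frame with one row per site: `protein`, `site_position`,
#'   `n_glycoforms`, `heterogeneity_bin`, and one `class_*` count column per
#'   glycan class.
#' @export
site_microheterogeneity <- function(records, mode = c("N", "O")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) {
    return(data.frame(protein = character(0), site_position = integer(0),
                      n_glycoforms = integer(0),
                      heterogeneity_bin = character(0)))
  }
  uniq <- records[!duplicated(paste(records$protein, records$site_position,
                                    records$composition, sep = "\r")), ,
                  drop = FALSE]
  cls <- if (mode == "N") classify_n(uniq$composition)
         else classify_o(uniq$composition)
  site <- paste(uniq$protein, uniq$site_position, sep = "\r")
  sf <- factor(site, levels = unique(site))
  first <- !duplicated(sf)
  out <- data.frame(protein = uniq$protein[first],
                    site_position = uniq$site_position[first],
                    n_glycoforms = as.integer(table(sf)[levels(sf)]),
                    stringsAsFactors = FALSE)
  out$heterogeneity_bin <- cut(out$n_glycoforms, c(0, 2, 10, Inf),
                               labels = c("low", "medium", "high"))
  tab <- table(sf, cls)[levels(sf), , drop = FALSE]
  for (lv in colnames(tab)) out[[paste0("class_", lv)]] <- as.integer(tab[, lv])
  rownames(out) <- NULL
  out
}

#' Fractional glycoform intensities per site
#'
#' A glycoform's fractional intensity is its MS1 intensity divided by the
#' summed MS1 intensity of all glycoforms at its site. The per-site top
#' (maximum) fraction is reported only for sites with at least
#' `min_glycoforms_top` glycoforms.
#'
#' @param records Glycopeptide records with `ms1_intensity`.
#' @param min_glycoforms_top Minimum glycoforms for a site to enter the
#'   top-fraction report (default 10).
#' @return List with `fractions` (per (site, glycoform): `fraction`, plus a
#'   `degenerate` flag for all-zero sites) and `top` (per qualifying site:
#'   `n_glycoforms`, `top_fraction`).
#' @export
fractional_intensity <- function(records, min_glycoforms_top = 10L) {
  site <- paste(records$protein, records$site_position, sep = "\r")
  sf <- factor(site, levels = unique(site))
  totals <- tapply(records$ms1_intensity, sf, sum, na.rm = TRUE)
  tot <- as.numeric(totals[site])
  degenerate <- !is.finite(tot) | tot <= 0
  frac <- data.frame(protein = records$protein,
                     site_position = records$site_position,
                     composition = records$composition,
                     fraction = ifelse(degenerate, NA_real_,
                                       records$ms1_intensity / tot),
                     degenerate = degenerate,
                     stringsAsFactors = FALSE)
  n_gf <- tapply(seq_along(site), sf, length)
  top_val <- tapply(frac$fraction, sf, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  keep <- as.integer(n_gf) >= min_glycoforms_top
  first <- !duplicated(sf)
  top <- data.frame(protein = records$protein[first][keep],
                    site_position = records$site_position[first][keep],
                    n_glycoforms = as.integer(n_gf)[keep],
                    top_fraction = as.numeric(top_val)[keep],
                    stringsAsFactors = FALSE)
  list(fractions = frac, top = top)
}

#' Label sites with low or high microheterogeneity
#'
#' Low: exactly one glycoform. High: glycoform count strictly above the
#' dataset's `percentile`-th percentile of glycoform counts. Everything else
#' is unlabeled. The threshold actually used is returned as an attribute.
#'
#' @param summaries Output of [site_microheterogeneity()].
#' @param percentile Percentile defining the high threshold (default 90).
#' @return `summaries` with an added `ml_label` column
#'   (`low`/`high`/`unlabeled`) and attribute `threshold`.
#' @export
label_low_high <- function(summaries, percentile = 90) {
  n <- summaries$n_glycoforms
  if (length(n) < 10L) warning("fewer than 10 sites; labels are unstable")
  thr <- as.numeric(stats::quantile(n, percentile / 100))
  if (stats::var(n) == 0) {
    warning("degenerate glycoform-count distribution; no high labels")
  }
  summaries$ml_label <- ifelse(n == 1L, "low",
                        ifelse(n > thr, "high", "unlabeled"))
  attr(summaries, "threshold") <- thr
  summaries
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation. For binary presence vectors the
#' concordant/discordant counts are obtained in closed form from the 2x2
#' table; general vectors use pairwise counting.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tau-b in \[-1, 1\]; `NA` when either vector is constant.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) return(NA_real_)
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_term(x); n2 <- tie_term(y)
  if (n1 == n0 || n2 == n0) return(NA_real_)
  if (all(x %in% c(0, 1)) && all(y %in% c(0, 1))) {
    n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
    n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
    s <- n11 * n00 - n10 * n01
  } else {
    s <- 0
    for (i in seq_len(n - 1L)) {
      dx <- sign(x[(i + 1L):n] - x[i])
      dy <- sign(y[(i + 1L):n] - y[i])
      s <- s + sum(dx * dy)
    }
  }
  s / sqrt((n0 - n1) * (n0 - n2))
}

# Binary site-by-composition presence matrix over the dataset-wide
# composition universe, split by protein.
.presence_by_protein <- function(records) {
  uniq <- records[!duplicated(paste(records$protein, records$site_position,
                                    records$composition, sep = "\r")), ,
                  drop = FALSE]
  universe <- sort(unique(uniq$composition))
  split_idx <- split(seq_len(nrow(uniq)), uniq$protein)
  lapply(split_idx, function(idx) {
    sites <- sort(unique(uniq$site_position[idx]))
    m <- matrix(0L, nrow = length(sites), ncol = length(universe),
                dimnames = list(sites, universe))
    m[cbind(match(uniq$site_position[idx], sites),
            match(uniq$composition[idx], universe))] <- 1L
    m
  })
}

#' Within-protein glycosylation-profile correlations
#'
#' For each glycosite, a binary vector over the union of all glycan
#' compositions observed in the dataset marks which compositions occur at the
#' site. For every pair of sites on the same protein (proteins with at least
#' two sites), the Kendall tau-b between the two presence vectors is
#' computed. Pairs with a constant vector are skipped and counted.
#'
#' @param records Glycopeptide records (`protein`, `site_position`,
#'   `composition`).
#' @return Data frame `protein`, `site_a`, `site_b`, `tau`, `source`
#'   (`"observed"`), with attribute `n_skipped` (constant-vector pairs).
#' @export
site_profile_correlation <- function(records) {
  mats <- .presence_by_protein(records)
  skipped <- 0L
  rows <- list()
  for (prot in names(mats)) {
    m <- mats[[prot]]
    if (nrow(m) < 2L) next
    cmb <- utils::combn(nrow(m), 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      tau <- kendall_tau_b(m[a, ], m[b, ])
      if (is.na(tau)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        protein = prot,
        site_a = as.integer(rownames(m)[a]),
        site_b = as.integer(rownames(m)[b]),
        tau = tau, source = "observed", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(0), site_a = integer(0),
               site_b = integer(0), tau = numeric(0), source = character(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Permutation null for glycosylation-profile similarity
#'
#' Each permutation redistributes the global multiset of (site, composition)
#' assignments by shuffling compositions across all site slots, preserving
#' every site's glycoform count exactly, then recomputes the within-protein
#' pair correlations. The observed and pooled shuffled tau distributions are
#' compared with a two-sided Wilcoxon test (rank-sum by default; the
#' Methods-style signed-rank pairing is available when the permutation
#' reproduces every observed pair).
#'
#' @param records Glycopeptide records.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Random seed (reproducible output).
#' @param test `"ranksum"` (default, unpaired) or `"signedrank"`.
#' @return List: `observed` and `shuffled` correlation tables, `p` (Wilcoxon
#'   p-value), `htest` (the full test object), `observed_median`,
#'   `shuffled_median`.
#' @export
shuffle_null <- function(records, n_perm, seed = 1L,
                         test = c("ranksum", "signedrank")) {
  test <- match.arg(test)
  if (!is.numeric(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  observed <- site_profile_correlation(records)
  uniq <- records[!duplicated(paste(records$protein, records$site_position,
                                    records$composition, sep = "\r")), ,
                  drop = FALSE]
  shuffled <- local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_perm), function(b) {
      perm <- uniq
      perm$composition <- sample(uniq$composition)
      sc <- site_profile_correlation(perm)
      if (nrow(sc)) { sc$source <- "shuffled"; sc$perm <- b }
      sc
    }))
  })
  ht <- if (test == "ranksum") {
    stats::wilcox.test(observed$tau, shuffled$tau, alternative = "two.sided")
  } else {
    key <- function(d) paste(d$protein, d$site_a, d$site_b)
    m <- merge(observed, stats::aggregate(tau ~ protein + site_a + site_b,
                                          shuffled, mean),
               by = c("protein", "site_a", "site_b"))
    stats::wilcox.test(m$tau.x, m$tau.y, paired = TRUE,
                       alternative = "two.sided")
  }
  list(observed = observed, shuffled = shuffled, p = ht$p.value, htest = ht,
       observed_median = stats::median(observed$tau),
       shuffled_median = stats::median(shuffled$tau))
}

#' Flag glycosites near known phosphosites
#'
#' N mode: a record is flagged when any phosphosite on the same protein lies
#' within `window` residues of the glycosite. O mode: within `window`
#' residues of the peptide start position (HCD data do not localize O-sites),
#' requiring a `peptide_start` column.
#'
#' @param records Glycopeptide records.
#' @param phospho Data frame of known phosphosites: `protein`, `position`.
#' @param mode `"N"` or `"O"`.
#' @param window Residue window (default 5, boundary inclusive).
#' @return `records` with a logical `near_phospho` column.
#' @export
phospho_proximity <- function(records, phospho, mode = c("N", "O"),
                              window = 5L) {
  mode <- match.arg(mode)
  anchor <- if (mode == "N") records$site_position else records$peptide_start
  if (is.null(anchor)) stop("O mode requires a 'peptide_start' column")
  pos_by_prot <- split(phospho$position, phospho$protein)
  records$near_phospho <- vapply(seq_len(nrow(records)), function(i) {
    pp <- pos_by_prot[[records$protein[i]]]
    !is.null(pp) && any(abs(pp - anchor[i]) <= window)
  }, logical(1))
  records
}

#' Contingency enrichment of categories across groups
#'
#' For every cell of a category-by-group count matrix (e.g. protein domains
#' by glycan classes), tests over/under-representation of the (category,
#' group) combination against the rest of the table with a two-sided Fisher
#' exact test. The log2 odds ratio uses a Haldane correction of 0.5 when any
#' cell of the 2x2 table is zero. P-values are Benjamini-Hochberg adjusted
#' across all cells.
#'
#' @param tab Count matrix (categories x groups), non-negative integers.
#' @param alpha Adjusted p-value significance cutoff (default 0.001).
#' @return Data frame per (category, group): the 2x2 counts `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `log2_odds_ratio`, `p`, `p_adj`, `significant`.
#' @export
contingency_enrichment <- function(tab, alpha = 0.001) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (is.null(rownames(tab))) rownames(tab) <- paste0("cat", seq_len(nrow(tab)))
  if (is.null(colnames(tab))) colnames(tab) <- paste0("grp", seq_len(ncol(tab)))
  total <- sum(tab); rs <- rowSums(tab); cs <- colSums(tab)
  grid <- expand.grid(category = rownames(tab), group = colnames(tab),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    i <- grid$category[k]; j <- grid$group[k]
    a <- tab[i, j]; b <- rs[i] - a; c_ <- cs[j] - a; d <- total - a - b - c_
    m <- matrix(c(a, b, c_, d), 2L)
    p <- stats::fisher.test(m)$p.value
    hc <- if (any(m == 0)) 0.5 else 0
    or <- ((a + hc) * (d + hc)) / ((b + hc) * (c_ + hc))
    data.frame(category = i, group = j, a = a, b = b, c = c_, d = d,
               odds_ratio = or, log2_odds_ratio = log2(or), p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- benjamini_hochberg(res$p)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}
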