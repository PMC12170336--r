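# Normalization, protein-abundance correction of glycopeptide intensities,
# and moderated differential abundance.

#' Normalize an intensity matrix
#'
#' Three per-sample monotone calibration methods:
#' \describe{
#'   \item{`vsn_like`}{inverse-hyperbolic-sine transform followed by a
#'     per-sample affine calibration that equalizes sample medians and median
#'     absolute deviations (a variance-stabilizing, log-like scale). Requires
#'     strictly positive intensities; the result is on a log-like scale.}
#'   \item{`quantile`}{forces identical per-sample value distributions
#'     (limma's quantile normalization).}
#'   \item{`median`}{multiplicative per-sample scaling equalizing medians
#'     (limma's median-value normalization); stays on the input scale.}
#' }
#'
#' @param x Numeric matrix, features x samples.
#' @param method One of `"vsn_like"`, `"quantile"`, `"median"`.
#' @return Normalized matrix with a `scale` attribute (`"normalized"` for
#'   `vsn_like`, otherwise the input scale).
#' @export
normalize_intensities <- function(x,
                                  method = c("vsn_like", "quantile",
                                             "median")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  out <- switch(method,
    quantile = {
      m <- limma::normalizeQuantiles(x)
      dimnames(m) <- dimnames(x)
      m
    },
    median = limma::normalizeMedianValues(x),
    vsn_like = {
      if (any(x[!is.na(x)] <= 0)) {
        stop("vsn_like normalization requires strictly positive intensities")
      }
      y <- asinh(x)
      med <- apply(y, 2L, stats::median, na.rm = TRUE)
      mad_ <- apply(y, 2L, stats::mad, na.rm = TRUE)
      mad_[mad_ == 0] <- 1
      target_med <- stats::median(med)
      target_mad <- stats::median(mad_)
      if (target_mad == 0) target_mad <- 1
      sweep(sweep(y, 2L, med, "-"), 2L, mad_ / target_mad, "/") + target_med
    })
  attr(out, "scale") <- if (method == "vsn_like") "normalized"
                        else attr(x, "scale")
  out
}

#' Correct glycopeptide intensities for protein abundance by regression
#'
#' Per glycopeptide, ordinary least squares of the glycopeptide log-intensity
#' on the matched protein log-intensity across samples; the corrected profile
#' is the residuals plus the glycopeptide's own mean (location preserved).
#' Glycopeptides without a matched protein pass through unchanged and are
#' flagged; a zero-variance protein profile gives slope 0 (also flagged),
#' i.e. the input row is returned unchanged.
#'
#' @param glyco Log-scale glycopeptide matrix, features x samples.
#' @param protein Log-scale protein matrix, proteins x samples (same sample
#'   order).
#' @param match Character vector, one protein id (row name of `protein`) per
#'   glycopeptide row; `NA` for unmatched.
#' @return Corrected matrix with attributes `unmatched` (logical per feature)
#'   and `zero_variance` (logical per feature).
#' @export
correct_by_regression <- function(glyco, protein, match) {
  glyco <- as.matrix(glyco); protein <- as.matrix(protein)
  stopifnot(length(match) == nrow(glyco), ncol(glyco) == ncol(protein))
  if (ncol(glyco) < 3L) stop("regression correction needs >= 3 samples")
  unmatched <- is.na(match) | !(match %in% rownames(protein))
  zero_var <- rep(FALSE, nrow(glyco))
  out <- glyco
  for (i in which(!unmatched)) {
    g <- glyco[i, ]; p <- protein[match[i], ]
    ok <- !is.na(g) & !is.na(p)
    if (sum(ok) < 3L) { unmatched[i] <- TRUE; next }
    vp <- stats::var(p[ok])
    if (vp == 0) { zero_var[i] <- TRUE; next }  # slope 0 -> unchanged
    slope <- stats::cov(g[ok], p[ok]) / vp
    out[i, ok] <- g[ok] - slope * (p[ok] - mean(p[ok]))
  }
  structure(out, unmatched = unmatched, zero_variance = zero_var)
}

#' Correct glycopeptide intensities for protein abundance by ratio
#'
#' Per sample, `corrected = ((g / p) / (median_g / median_p)) * median_g`,
#' where `median_g` and `median_p` are the per-sample medians of the matched
#' glycopeptide and protein intensities. Operates on raw-scale positive
#' intensities; cells with protein intensity 0 become missing. The output is
#' invariant to global rescaling of the protein matrix.
#'
#' @inheritParams correct_by_regression
#' @param glyco Raw-scale glycopeptide matrix.
#' @param protein Raw-scale protein matrix.
#' @return Corrected matrix; unmatched glycopeptides pass through unchanged
#'   (flagged in the `unmatched` attribute).
#' @export
correct_by_ratio <- function(glyco, protein, match) {
  glyco <- as.matrix(glyco); protein <- as.matrix(protein)
  stopifnot(length(match) == nrow(glyco), ncol(glyco) == ncol(protein))
  unmatched <- is.na(match) | !(match %in% rownames(protein))
  if (!any(!unmatched)) stop("no glycopeptide has a matched protein")
  p_aligned <- protein[ifelse(unmatched, rownames(protein)[1L], match), ,
                       drop = FALSE]
  p_aligned[unmatched, ] <- NA_real_
  med_g <- apply(glyco[!unmatched, , drop = FALSE], 2L, stats::median,
                 na.rm = TRUE)
  med_p <- apply(p_aligned[!unmatched, , drop = FALSE], 2L, stats::median,
                 na.rm = TRUE)
  if (any(!is.finite(med_g)) || any(!is.finite(med_p)) ||
      any(med_g <= 0) || any(med_p <= 0)) {
    stop("per-sample medians must be strictly positive")
  }
  p_zero <- !is.na(p_aligned) & p_aligned == 0
  p_aligned[p_zero] <- NA_real_
  ratio <- glyco / p_aligned
  out <- sweep(sweep(ratio, 2L, med_g / med_p, "/"), 2L, med_g, "*")
  out[unmatched, ] <- glyco[unmatched, ]
  structure(out, unmatched = unmatched, n_zero_protein = sum(p_zero))
}

#' Moderated differential abundance
#'
#' Fits a per-feature linear model over the sample design (condition, plus
#' replicate as an additive covariate when declared) with empirical-Bayes
#' variance moderation, computes per-contrast log2 fold changes and moderated
#' t p-values, adjusts with Benjamini-Hochberg per contrast, and flags
#' significance as |log2 FC| > `lfc_threshold` and adjusted p < `alpha`.
#' Only complete-case features (no missing values) are tested.
#'
#' @param x Log-scale intensity matrix, features x samples.
#' @param design Data frame with one row per sample: `condition` and
#'   optionally `replicate` (and other columns, ignored).
#' @param contrasts List of two-element character vectors
#'   `c(level_a, level_b)`; the fold change reported is `a - b`.
#' @param lfc_threshold Absolute log2 fold-change threshold (default
#'   `log2(1.5)`; use `log2(2)` for the tissue-comparison preset).
#' @param alpha Adjusted p-value threshold (default 0.05).
#' @return Data frame with one row per (feature, contrast): `feature`,
#'   `contrast`, `log2_fc`, `p_raw`, `p_adj`, `significant`. The number of
#'   features dropped as incomplete is in attribute `n_incomplete`.
#' @export
differential <- function(x, design, contrasts,
                         lfc_threshold = log2(1.5), alpha = 0.05) {
  x <- as.matrix(x)
  stopifnot(nrow(design) == ncol(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("feature_", seq_len(nrow(x)))
  if (!is.list(contrasts)) contrasts <- list(contrasts)
  cond <- factor(design$condition)
  for (ct in contrasts) {
    if (length(ct) != 2L || !all(ct %in% levels(cond))) {
      stop("contrast references absent condition level: ",
           paste(ct, collapse = " vs "))
    }
  }
  complete <- stats::complete.cases(x)
  xx <- x[complete, , drop = FALSE]
  if (nrow(xx) == 0L) stop("no complete-case features to test")
  has_rep <- !is.null(design$replicate) &&
    length(unique(design$replicate)) > 1L
  mm <- if (has_rep) {
    stats::model.matrix(~ 0 + cond + factor(design$replicate))
  } else {
    stats::model.matrix(~ 0 + cond)
  }
  colnames(mm)[seq_along(levels(cond))] <- levels(cond)
  fit <- limma::lmFit(xx, mm)
  cm <- matrix(0, nrow = ncol(mm), ncol = length(contrasts),
               dimnames = list(colnames(mm), vapply(contrasts, function(ct)
                 paste(ct, collapse = "_vs_"), character(1))))
  for (j in seq_along(contrasts)) {
    cm[contrasts[[j]][1L], j] <- 1
    cm[contrasts[[j]][2L], j] <- -1
  }
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  res <- do.call(rbind, lapply(seq_along(contrasts), function(j) {
    lfc <- fit2$coefficients[, j]
    p <- fit2$p.value[, j]
    data.frame(feature = rownames(xx),
               contrast = colnames(cm)[j],
               log2_fc = as.numeric(lfc),
               p_raw = as.numeric(p),
               p_adj = benjamini_hochberg(as.numeric(p)),
               stringsAsFactors = FALSE)
  }))
  res$significant <- abs(res$log2_fc) > lfc_threshold & res$p_adj < alpha
  rownames(res) <- NULL
  attr(res, "n_incomplete") <- sum(!complete)
  attr(res, "lfc_threshold") <- lfc_threshold
  attr(res, "alpha") <- alpha
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, capped at 1 and monotone in the
#' sorted p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise at least as large as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
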