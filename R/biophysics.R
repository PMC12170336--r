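# Glycoform solubility differentials (NP40 vs SDS) and thermal-profile
# delta-AUC with internal-reference replicate alignment.

#' Per-feature solubility ratios
#'
#' log2 ratio of the mild-detergent (NP40) to the denaturing-detergent (SDS)
#' intensity, per feature and replicate. Cells where either side is missing
#' or non-positive become missing and are counted.
#'
#' @param np40,sds Replicate-matched positive intensity matrices (same
#'   dimensions and order).
#' @return Matrix of log2 ratios with attribute `n_undefined`.
#' @export
solubility_ratio <- function(np40, sds) {
  np40 <- as.matrix(np40); sds <- as.matrix(sds)
  stopifnot(identical(dim(np40), dim(sds)))
  bad <- is.na(np40) | is.na(sds) | np40 <= 0 | sds <= 0
  out <- log2(np40 / sds)
  out[bad] <- NA_real_
  structure(out, n_undefined = sum(bad))
}

#' Differential glycoform solubility
#'
#' Compares each glycoform's solubility ratio to the solubility ratio of its
#' parent protein across replicates. Only glycopeptides with a matched
#' measured protein are used; both ratio sets are median-normalized per
#' replicate (per-sample medians equalized on the log scale) before a
#' moderated test of the per-replicate difference (glycoform minus protein).
#' Significance: |log2 FC| > `lfc_threshold` and BH-adjusted p < `alpha`.
#'
#' @param glyco_ratio Glycoform log2 NP40/SDS matrix, features x replicates.
#' @param protein_ratio Protein log2 NP40/SDS matrix, proteins x replicates
#'   (row names = protein ids).
#' @param match Protein id per glycoform row (`NA` when unmatched).
#' @param lfc_threshold Effect-size cutoff (default `log2(1.5)`).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Data frame per matched glycoform: `feature`, `log2_fc`
#'   (glycoform solubility minus protein solubility), `p_raw`, `p_adj`,
#'   `significant`. Attribute `n_unmatched` counts excluded glycoforms.
#' @export
differential_solubility <- function(glyco_ratio, protein_ratio, match,
                                    lfc_threshold = log2(1.5),
                                    alpha = 0.05) {
  glyco_ratio <- as.matrix(glyco_ratio)
  protein_ratio <- as.matrix(protein_ratio)
  stopifnot(length(match) == nrow(glyco_ratio),
            ncol(glyco_ratio) == ncol(protein_ratio))
  if (is.null(rownames(glyco_ratio))) {
    rownames(glyco_ratio) <- paste0("glycoform_", seq_len(nrow(glyco_ratio)))
  }
  matched <- !is.na(match) & match %in% rownames(protein_ratio)
  # log2 ratios center at 0: per-replicate median subtraction removes both
  # between-replicate drifts and any global offset of either ratio set
  center <- function(m) {
    sweep(m, 2L, apply(m, 2L, stats::median, na.rm = TRUE), "-")
  }
  g <- center(glyco_ratio[matched, , drop = FALSE])
  p <- center(protein_ratio)[match[matched], , drop = FALSE]
  d <- g - p
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, ncol(d), 1L)))
  res <- data.frame(feature = rownames(d),
                    log2_fc = as.numeric(fit$coefficients[, 1L]),
                    p_raw = as.numeric(fit$p.value[, 1L]),
                    stringsAsFactors = FALSE)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res$significant <- abs(res$log2_fc) > lfc_threshold & res$p_adj < alpha
  rownames(res) <- NULL
  attr(res, "n_unmatched") <- sum(!matched)
  res
}

#' Align thermal melting series across multiplex sets
#'
#' Removes the batch effect of the multiplex set used for each replicate by
#' an internal-reference scaling computed from the first (lowest)
#' temperature: each set's scaling factor is the across-set mean protein
#' intensity at the first temperature divided by that set's mean (proteins
#' missing at the first temperature are excluded from the factor). All
#' intensities in a set are multiplied by its factor; the scaled data are
#' then quantile-normalized across (set, condition) sample columns over
#' protein-by-temperature rows, preserving melting shapes.
#'
#' @param melt Long data frame: `protein`, `set`, `condition`,
#'   `temperature`, `intensity`. Temperatures must form a common increasing
#'   grid.
#' @param quantile_normalize Apply the quantile step after scaling (default
#'   `TRUE`).
#' @return The aligned long data frame (same columns, `intensity` replaced,
#'   plus `normalized = TRUE`), with attribute `factors` (named per set).
#' @export
tpp_align <- function(melt, quantile_normalize = TRUE) {
  need <- c("protein", "set", "condition", "temperature", "intensity")
  if (!all(need %in% names(melt))) {
    stop("melt table requires columns: ", paste(need, collapse = ", "))
  }
  temps <- sort(unique(melt$temperature))
  t1 <- temps[1L]
  first <- melt[melt$temperature == t1 & !is.na(melt$intensity), ,
                drop = FALSE]
  if (nrow(first) == 0L) stop("no intensities at the first temperature")
  overall <- mean(first$intensity)
  per_set <- tapply(first$intensity, first$set, mean)
  factors <- stats::setNames(as.numeric(overall / per_set), names(per_set))
  out <- melt
  out$intensity <- out$intensity * as.numeric(factors[as.character(out$set)])
  if (quantile_normalize) {
    sample_key <- paste(out$set, out$condition, sep = "\r")
    row_key <- paste(out$protein, out$temperature, sep = "\r")
    samples <- unique(sample_key); rows <- unique(row_key)
    m <- matrix(NA_real_, length(rows), length(samples),
                dimnames = list(rows, samples))
    m[cbind(match(row_key, rows), match(sample_key, samples))] <-
      out$intensity
    m <- limma::normalizeQuantiles(m)
    out$intensity <- m[cbind(match(row_key, rows),
                             match(sample_key, samples))]
  }
  out$normalized <- TRUE
  attr(out, "factors") <- factors
  out
}

#' Delta-AUC between two melting series
#'
#' Each series is anchored by subtracting its own mean of the first two
#' temperature intensities from every temperature (removing the abundance
#' offset so only thermal (de)stabilization remains); the delta-AUC is the
#' plain sum over temperatures of the anchored difference (series A minus
#' series B). Identical series give 0 and the measure is antisymmetric.
#'
#' @param a,b Numeric intensity vectors on the same increasing temperature
#'   grid (length >= 2).
#' @return A single delta-AUC value.
#' @export
delta_auc <- function(a, b) {
  if (length(a) != length(b)) stop("series must share the temperature grid")
  if (length(a) < 2L) stop("need at least two temperatures")
  anchor <- function(v) v - mean(v[1:2])
  sum(anchor(a) - anchor(b))
}

#' Per-protein delta-AUC from an aligned melt table
#'
#' Averages replicate sets per (protein, condition, temperature), then
#' applies [delta_auc()] per protein between the two conditions.
#'
#' @param melt Aligned long melt table (see [tpp_align()]).
#' @param condition_a,condition_b Condition labels; delta-AUC is A minus B.
#' @return Data frame `protein`, `delta_auc` (proteins lacking a full grid
#'   in either condition are dropped).
#' @export
tpp_delta_auc <- function(melt, condition_a, condition_b) {
  temps <- sort(unique(melt$temperature))
  avg <- stats::aggregate(intensity ~ protein + condition + temperature,
                          melt, mean)
  out <- do.call(rbind, lapply(unique(avg$protein), function(pr) {
    aa <- avg[avg$protein == pr & avg$condition == condition_a, ]
    bb <- avg[avg$protein == pr & avg$condition == condition_b, ]
    aa <- aa[order(aa$temperature), ]; bb <- bb[order(bb$temperature), ]
    if (nrow(aa) != length(temps) || nrow(bb) != length(temps)) return(NULL)
    data.frame(protein = pr,
               delta_auc = delta_auc(aa$intensity, bb$intensity),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
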