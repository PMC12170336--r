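# Tissue-specificity scoring of glycosylation patterns and per-tissue
# composition summaries.

#' Cross-tissue conservation of site glycosylation patterns
#'
#' For every glycosite with more than `min_glycopeptides` quantified
#' glycopeptides (strictly greater by default), the site's glycosylation
#' pattern per tissue is the vector of its glycopeptides' mean intensities
#' across that tissue's replicates, rescaled to relative intensities (sum 1).
#' Patterns are compared between every tissue pair with Pearson correlation;
#' the per-site mean over pairs is classified against the dataset mean of
#' mean correlations (always recomputed from the data): sites below the mean
#' are tissue `specific`, the rest `conserved`.
#'
#' @param x Intensity matrix (protein-corrected, positive scale), features x
#'   samples.
#' @param design Data frame per sample with `tissue` (and anything else,
#'   ignored; replicates are averaged within tissue).
#' @param features Data frame per feature row of `x`: `protein`,
#'   `site_position`.
#' @param min_glycopeptides Glycopeptide count threshold (default 5).
#' @param strict If `TRUE` (default) require strictly more than
#'   `min_glycopeptides`; `FALSE` gives the at-least variant.
#' @return Data frame per qualifying site: `protein`, `site_position`,
#'   `n_glycopeptides`, one `cor_*` column per tissue pair,
#'   `mean_correlation`, `incomplete` (some tissue pair skipped),
#'   `specificity`. Attribute `cutoff` holds the dataset mean used.
#' @export
site_tissue_correlation <- function(x, design, features,
                                    min_glycopeptides = 5L, strict = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(design) == ncol(x), nrow(features) == nrow(x))
  tissues <- unique(as.character(design$tissue))
  if (length(tissues) < 2L) stop("need at least two tissues")
  tmeans <- sapply(tissues, function(tt)
    rowMeans(x[, design$tissue == tt, drop = FALSE], na.rm = TRUE))
  site <- paste(features$protein, features$site_position, sep = "\r")
  idx_by_site <- split(seq_len(nrow(x)), site)
  n_gp <- lengths(idx_by_site)
  qual <- if (strict) n_gp > min_glycopeptides else n_gp >= min_glycopeptides
  idx_by_site <- idx_by_site[qual]
  if (length(idx_by_site) == 0L) stop("no site passes the glycopeptide count threshold")
  pairs <- utils::combn(tissues, 2L)
  pair_names <- paste0("cor_", pairs[1L, ], "_", pairs[2L, ])
  rows <- lapply(names(idx_by_site), function(sk) {
    idx <- idx_by_site[[sk]]
    rel <- apply(tmeans[idx, , drop = FALSE], 2L, function(v) {
      s <- sum(v, na.rm = TRUE)
      if (!is.finite(s) || s <= 0) rep(NA_real_, length(v)) else v / s
    })
    cors <- vapply(seq_len(ncol(pairs)), function(k) {
      a <- rel[, pairs[1L, k]]; b <- rel[, pairs[2L, k]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(a[ok], b[ok])
    }, numeric(1))
    parts <- strsplit(sk, "\r", fixed = TRUE)[[1L]]
    out <- data.frame(protein = parts[1L],
                      site_position = as.integer(parts[2L]),
                      n_glycopeptides = length(idx),
                      stringsAsFactors = FALSE)
    for (k in seq_along(pair_names)) out[[pair_names[k]]] <- cors[k]
    out$mean_correlation <- mean(cors, na.rm = TRUE)
    out$incomplete <- anyNA(cors)
    out
  })
  res <- do.call(rbind, rows)
  res <- res[is.finite(res$mean_correlation), , drop = FALSE]
  cutoff <- mean(res$mean_correlation)
  res$specificity <- ifelse(res$mean_correlation < cutoff, "specific",
                            "conserved")
  rownames(res) <- NULL
  attr(res, "cutoff") <- cutoff
  res
}

#' Summed glycan-class intensity per tissue
#'
#' Summed intensities of all quantified glycopeptides per glycan class and
#' tissue, as a proxy for class abundance, plus per-tissue fractions.
#'
#' @param x Intensity matrix, features x samples.
#' @param design Sample design with `tissue`.
#' @param classes Glycan class per feature (character or factor).
#' @return Data frame `tissue`, `class`, `total_intensity`, `fraction`
#'   (fractions sum to 1 within tissue).
#' @export
class_abundance_by_tissue <- function(x, design, classes) {
  x <- as.matrix(x)
  stopifnot(nrow(design) == ncol(x), length(classes) == nrow(x))
  tissues <- unique(as.character(design$tissue))
  cls <- factor(classes)
  out <- do.call(rbind, lapply(tissues, function(tt) {
    tot <- rowSums(x[, design$tissue == tt, drop = FALSE], na.rm = TRUE)
    sums <- tapply(tot, cls, sum)
    sums[is.na(sums)] <- 0
    data.frame(tissue = tt, class = names(sums),
               total_intensity = as.numeric(sums),
               fraction = as.numeric(sums) / sum(sums),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tissue-characteristic high-abundance compositions
#'
#' Per tissue, the fractional abundance of each glycopeptide is its summed
#' intensity divided by the tissue total. The top `top_percent` of
#' glycopeptides by fractional abundance (ties broken by feature id) are
#' reported with composition, mass and class, plus per-tissue summary
#' statistics (median glycan mass of the top set, fraction of fucosylated
#' compositions).
#'
#' @param x Intensity matrix, features x samples (row names = feature ids).
#' @param design Sample design with `tissue`.
#' @param features Data frame per feature: `composition` (class and mass are
#'   derived from it).
#' @param top_percent Percentage of glycopeptides to keep (default 1).
#' @param mode Classification mode for the class labels.
#' @return List with `top` (per tissue, the selected glycopeptides) and
#'   `summary` (per tissue: `n_top`, `median_mass`, `fucosylated_fraction`,
#'   `overall_median_mass`).
#' @export
top_fraction_compositions <- function(x, design, features, top_percent = 1,
                                      mode = c("N", "O")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  stopifnot(nrow(design) == ncol(x), nrow(features) == nrow(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("feature_", seq_len(nrow(x)))
  if (nrow(x) < 100L) {
    warning("fewer than 100 glycopeptides; top set is max(1, round)")
  }
  comp <- validate_composition(features$composition)
  mass <- glycan_mass(comp)
  cls <- as.character(if (mode == "N") classify_n(comp) else classify_o(comp))
  fuc <- comp$fuc > 0L
  tissues <- unique(as.character(design$tissue))
  n_top <- max(1L, round(nrow(x) * top_percent / 100))
  top <- do.call(rbind, lapply(tissues, function(tt) {
    tot <- rowSums(x[, design$tissue == tt, drop = FALSE], na.rm = TRUE)
    frac <- tot / sum(tot)
    ord <- order(-frac, rownames(x))
    sel <- ord[seq_len(n_top)]
    data.frame(tissue = tt, feature = rownames(x)[sel],
               composition = features$composition[sel],
               mass = mass[sel], class = cls[sel],
               fractional_abundance = frac[sel],
               fucosylated = fuc[sel], stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(tissues, function(tt) {
    tb <- top[top$tissue == tt, , drop = FALSE]
    data.frame(tissue = tt, n_top = nrow(tb),
               median_mass = stats::median(tb$mass),
               fucosylated_fraction = mean(tb$fucosylated),
               overall_median_mass = stats::median(mass),
               stringsAsFactors = FALSE)
  }))
  rownames(top) <- rownames(summary) <- NULL
  list(top = top, summary = summary)
}
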