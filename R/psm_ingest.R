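# Ingestion of search-engine glyco-PSM exports: reading, identification
# filters, collapsing to unique glycopeptides, reporter channel-leak masking.

#' Default PSM column map
#'
#' Maps the package's standardized field names to the column headers of a
#' typical open-search PSM export (FragPipe psm.tsv dialect). Reporter
#' channel columns are matched separately by `reporter_pattern` in
#' [read_psm_table()].
#'
#' @return Named character vector (standard name -> file column header).
#' @export
default_psm_columns <- function() {
  c(peptide     = "Peptide",
    protein     = "Protein ID",
    site        = "Glycan Site",
    composition = "Total Glycan Composition",
    glycan_q    = "Glycan q-value",
    ms1         = "Intensity",
    spectrum    = "Spectrum")
}

#' Read a glyco-PSM table
#'
#' Reads a tab-separated PSM export. Rows without a glycan assignment (empty
#' composition) are dropped and counted; malformed rows (non-positive or
#' missing site, negative intensity) are dropped and reported with line
#' numbers.
#'
#' @param path File path.
#' @param mode `"N"` or `"O"` glycosylation mode (recorded on the result).
#' @param columns Column map as from [default_psm_columns()]; the `spectrum`
#'   entry is optional in the file.
#' @param reporter_pattern Regular expression identifying TMT reporter
#'   columns; matched columns are renamed `channel_<label>`.
#' @return Data frame of PSMs with standardized columns `peptide`, `protein`,
#'   `site_position`, `composition`, `glycan_q`, `ms1_intensity`,
#'   `spectrum_id`, plus one `channel_*` column per reporter channel.
#'   Attributes: `mode`, `channels`, `n_no_glycan`, `bad_rows`.
#' @export
read_psm_table <- function(path, mode = c("N", "O"),
                           columns = default_psm_columns(),
                           reporter_pattern = "^channel[ _.]") {
  mode <- match.arg(mode)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mandatory <- c("peptide", "protein", "site", "composition", "glycan_q",
                 "ms1")
  for (f in mandatory) {
    if (!columns[[f]] %in% names(raw)) {
      stop(sprintf("missing mandatory column '%s' in %s", columns[[f]], path))
    }
  }
  rep_cols <- grep(reporter_pattern, names(raw), value = TRUE)
  channels <- sub(reporter_pattern, "", rep_cols)
  out <- data.frame(
    peptide = as.character(raw[[columns[["peptide"]]]]),
    protein = as.character(raw[[columns[["protein"]]]]),
    site_position = suppressWarnings(as.integer(raw[[columns[["site"]]]])),
    composition = as.character(raw[[columns[["composition"]]]]),
    glycan_q = suppressWarnings(as.numeric(raw[[columns[["glycan_q"]]]])),
    ms1_intensity = suppressWarnings(as.numeric(raw[[columns[["ms1"]]]])),
    stringsAsFactors = FALSE)
  out$spectrum_id <- if (!is.null(columns[["spectrum"]]) &&
                         columns[["spectrum"]] %in% names(raw)) {
    as.character(raw[[columns[["spectrum"]]]])
  } else {
    sprintf("psm_%06d", seq_len(nrow(raw)))
  }
  if ("Peptide Start" %in% names(raw)) {
    out$peptide_start <- suppressWarnings(as.integer(raw[["Peptide Start"]]))
  }
  for (i in seq_along(rep_cols)) {
    out[[paste0("channel_", channels[i])]] <-
      suppressWarnings(as.numeric(raw[[rep_cols[i]]]))
  }
  no_glycan <- is.na(out$composition) | !nzchar(trimws(out$composition))
  bad <- !no_glycan & (is.na(out$site_position) | out$site_position < 1L |
                       (!is.na(out$ms1_intensity) & out$ms1_intensity < 0))
  if (any(bad)) {
    message(sprintf("dropping %d malformed PSM row(s) at line(s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10L), collapse = ", ")))
  }
  res <- out[!no_glycan & !bad, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, mode = mode, channels = channels,
            n_no_glycan = sum(no_glycan), bad_rows = which(bad))
}

#' Write a glyco-PSM table
#'
#' Writes PSMs back to the tab-separated dialect read by [read_psm_table()]
#' (round trip).
#'
#' @param psms PSM data frame from [read_psm_table()] or the simulator.
#' @param path Output file path.
#' @param columns Column map, see [default_psm_columns()].
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, columns = default_psm_columns()) {
  rep_cols <- grep("^channel_", names(psms), value = TRUE)
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = psms$peptide, b = psms$protein, c = psms$site_position,
    d = psms$composition, e = psms$glycan_q, f = psms$ms1_intensity,
    g = psms$spectrum_id)
  names(out) <- unname(columns[c("peptide", "protein", "site", "composition",
                                 "glycan_q", "ms1", "spectrum")])
  if (!is.null(psms$peptide_start)) out[["Peptide Start"]] <- psms$peptide_start
  for (rc in rep_cols) out[[sub("^channel_", "channel ", rc)]] <- psms[[rc]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identification quality filters
#'
#' Keeps PSMs with glycan q-value at most `q_max`. In O mode additionally
#' removes peptides whose sequence contains the N-glycosylation sequon
#' (N-X-S/T, to prevent N/O misassignment) and PSMs without a glycan target
#' match (missing q-value). Each dropped PSM is counted under exactly one
#' reason.
#'
#' @param psms PSM data frame.
#' @param mode `"N"` or `"O"`; defaults to the `mode` attribute of `psms`.
#' @param q_max Glycan q-value cutoff (default 0.05).
#' @param sequon_exclude_proline If `TRUE`, the sequon pattern excludes
#'   proline at X (N-[not P]-S/T); default is the literal N-X-S/T.
#' @return Filtered PSM data frame with a `filter_report` attribute: a data
#'   frame of drop reasons and counts whose total equals rows in minus rows
#'   out.
#' @export
qc_filter <- function(psms, mode = attr(psms, "mode"), q_max = 0.05,
                      sequon_exclude_proline = FALSE) {
  if (is.null(mode)) mode <- "N"
  mode <- match.arg(mode, c("N", "O"))
  reason <- rep(NA_character_, nrow(psms))
  reason[is.na(psms$composition) |
           !nzchar(trimws(psms$composition))] <- "no_glycan"
  no_target <- is.na(reason) & is.na(psms$glycan_q)
  if (mode == "O") {
    pat <- if (sequon_exclude_proline) "N[^P][ST]" else "N[A-Z][ST]"
    sequon <- grepl(pat, psms$peptide)
    reason[is.na(reason) & sequon] <- "n_sequon"
    reason[is.na(reason) & no_target] <- "no_target_match"
  } else {
    reason[no_target] <- "no_target_match"
  }
  reason[is.na(reason) & psms$glycan_q > q_max] <- "q_value"
  keep <- is.na(reason)
  report <- as.data.frame(table(reason = reason[!keep]),
                          stringsAsFactors = FALSE)
  names(report) <- c("reason", "n")
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("mode", "channels")] <-
    attributes(psms)[c("mode", "channels")]
  attr(out, "filter_report") <- report
  out
}

#' Collapse PSMs to unique glycopeptides
#'
#' A unique glycopeptide is a unique (peptide sequence, glycan composition)
#' pair. MS1 intensity is aggregated with `max` over the group's PSMs (peak
#' height proxy) and reporter intensities with element-wise sums (additive
#' signal); both are configurable. The site is taken from the grouped PSMs
#' and must be consistent within a group.
#'
#' @param psms Filtered PSM data frame.
#' @param ms1_aggregate `"max"` (default) or `"sum"`.
#' @param reporter_aggregate `"sum"` (default) or `"max"`.
#' @return Data frame of glycopeptide records: `peptide`, `protein`,
#'   `site_position`, `composition`, `ms1_intensity`, `n_psms`, channel
#'   columns.
#' @export
collapse_unique <- function(psms, ms1_aggregate = c("max", "sum"),
                            reporter_aggregate = c("sum", "max")) {
  ms1_aggregate <- match.arg(ms1_aggregate)
  reporter_aggregate <- match.arg(reporter_aggregate)
  key <- paste(psms$peptide, psms$composition, sep = "\r")
  grp <- factor(key, levels = unique(key))
  site_chk <- tapply(paste(psms$protein, psms$site_position),
                     grp, function(v) length(unique(v)))
  if (any(site_chk > 1L)) {
    bad <- names(site_chk)[site_chk > 1L]
    stop("conflicting protein/site within glycopeptide group(s): ",
         paste(gsub("\r", " / ", utils::head(bad, 5L)), collapse = "; "))
  }
  first <- !duplicated(grp)
  agg_fun <- function(v, how) {
    if (all(is.na(v))) return(NA_real_)
    if (how == "max") max(v, na.rm = TRUE) else sum(v, na.rm = TRUE)
  }
  out <- psms[first, c("peptide", "protein", "site_position", "composition"),
              drop = FALSE]
  out$ms1_intensity <- as.numeric(
    tapply(psms$ms1_intensity, grp, agg_fun, how = ms1_aggregate))
  out$n_psms <- as.integer(table(grp)[levels(grp)])
  if (!is.null(psms$peptide_start)) out$peptide_start <- psms$peptide_start[first]
  for (rc in grep("^channel_", names(psms), value = TRUE)) {
    out[[rc]] <- as.numeric(
      tapply(psms[[rc]], grp, agg_fun, how = reporter_aggregate))
  }
  rownames(out) <- NULL
  attributes(out)[c("mode", "channels")] <-
    attributes(psms)[c("mode", "channels")]
  out
}

#' Extract the reporter-intensity matrix from glycopeptide records
#'
#' @param records Glycopeptide record data frame with `channel_*` columns.
#' @param feature_id Optional feature id column values used as row names;
#'   default `peptide` + `composition`.
#' @return Numeric matrix, features x channels.
#' @export
reporter_matrix <- function(records, feature_id = NULL) {
  rep_cols <- grep("^channel_", names(records), value = TRUE)
  m <- as.matrix(records[, rep_cols, drop = FALSE])
  colnames(m) <- sub("^channel_", "", rep_cols)
  rownames(m) <- if (is.null(feature_id)) {
    paste(records$peptide, records$composition, sep = "|")
  } else feature_id
  m
}

#' Mask reporter channel leak
#'
#' Per feature, reporter channels with intensity strictly below 1/16 of that
#' feature's maximum channel are treated as cross-channel leak and set to
#' missing (a channel at exactly the 1/16 boundary is kept). Features with no
#' positive channel are dropped. Masking is idempotent.
#'
#' @param x Numeric matrix, features x channels.
#' @param threshold Ratio to the per-feature maximum below which a channel is
#'   masked (default 1/16).
#' @param remove_features If `TRUE`, features with any masked channel are
#'   dropped entirely rather than keeping the remaining channels.
#' @return The masked matrix, with a `mask_report` attribute: list with
#'   `n_masked` (cells set missing), `dropped` (row names of dropped
#'   features).
#' @export
mask_channel_leak <- function(x, threshold = 1 / 16,
                              remove_features = FALSE) {
  x <- as.matrix(x)
  mx <- apply(x, 1L, function(v) if (all(is.na(v))) NA_real_
              else max(v, na.rm = TRUE))
  dead <- is.na(mx) | mx <= 0
  mask <- sweep(x, 1L, mx * threshold, "<") & !is.na(x)
  mask[dead, ] <- FALSE
  n_masked <- sum(mask)
  x[mask] <- NA_real_
  all_masked <- apply(x, 1L, function(v) all(is.na(v)))
  drop <- dead | all_masked
  if (remove_features) drop <- drop | apply(mask, 1L, any)
  out <- x[!drop, , drop = FALSE]
  attr(out, "mask_report") <- list(n_masked = n_masked,
                                   dropped = rownames(x)[drop])
  out
}

#' Read a sample design table
#'
#' Tab-separated table with one row per reporter channel. Requires columns
#' `channel` and `condition`; optional `replicate`, `tissue`, `time`,
#' `treatment`.
#'
#' @param path File path.
#' @return Data frame, channels unique.
#' @export
read_sample_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("channel", "condition") %in% names(d))) {
    stop("sample design requires 'channel' and 'condition' columns")
  }
  d$channel <- as.character(d$channel)
  if (anyDuplicated(d$channel)) stop("duplicate channel labels in design")
  d
}
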