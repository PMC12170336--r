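# Glycan composition vocabulary: parsing, mass, hierarchical classification,
# and the composition-database filtering rules.

#' Residue keys modeled for glycan compositions
#'
#' The seven monosaccharide/modification keys tracked by the package, in
#' canonical order: HexNAc, Hex, Fuc, NeuAc, NeuGc, Phospho, Sulfo.
#'
#' @format Character vector of length 7 (lower-case keys).
#' @export
glycan_residues <- c("hexnac", "hex", "fuc", "neuac", "neugc",
                     "phospho", "sulfo")

# Display spellings used when formatting compositions.
.residue_display <- c(hexnac = "HexNAc", hex = "Hex", fuc = "Fuc",
                      neuac = "NeuAc", neugc = "NeuGc",
                      phospho = "Phospho", sulfo = "Sulfo")

# Standard monoisotopic residue masses (Da).
.residue_masses <- c(hexnac = 203.07937, hex = 162.05282, fuc = 146.05791,
                     neuac = 291.09542, neugc = 307.09033,
                     phospho = 79.96633, sulfo = 79.95682)

# Parse-time synonyms (lower-cased token -> canonical key). dHex is the
# deoxyhexose spelling of fucose used by some search exports.
.residue_synonyms <- c(hexnac = "hexnac", hex = "hex", fuc = "fuc",
                       dhex = "fuc", neuac = "neuac", neugc = "neugc",
                       phospho = "phospho", sulfo = "sulfo")

#' N- and O-glycan class labels
#'
#' Class labels assigned by [classify_n()] and [classify_o()], in hierarchy
#' order (the first matching class wins).
#'
#' @name glycan_classes
#' @export
n_glycan_classes <- c("phospho", "sialylated", "fucosylated", "high_mannose",
                      "paucimannose", "small", "complex_hybrid")

#' @rdname glycan_classes
#' @export
o_glycan_classes <- c("o_phospho", "o_sialylated", "o_fucosylated",
                      "o_sulfated", "o_glcnac", "o_hexose", "o_hybrid")

#' Parse glycan composition strings
#'
#' Parses strings of repeated `Name(count)` tokens, e.g. `"HexNAc(2)Hex(5)"`,
#' into a residue-count table. Recognized residue names (case-insensitive):
#' HexNAc, Hex, Fuc (synonym dHex), NeuAc, NeuGc, Phospho, Sulfo.
#' Residues not mentioned get count 0; duplicated tokens are summed.
#'
#' @param x Character vector of composition strings.
#' @return A data frame with one row per input string and one integer column
#'   per residue key in [glycan_residues].
#' @examples
#' parse_composition("HexNAc(2)Hex(5)")
#' parse_composition(c("HexNAc(4)Hex(5)Fuc(1)NeuAc(2)", "Hex(1)dHex(1)"))
#' @export
parse_composition <- function(x) {
  if (length(x) == 0L) {
    out <- as.data.frame(matrix(integer(0), nrow = 0,
                                ncol = length(glycan_residues)))
    names(out) <- glycan_residues
    return(out)
  }
  x <- as.character(x)
  if (anyNA(x) || any(!nzchar(trimws(x)))) {
    stop("cannot parse empty or missing glycan composition string")
  }
  counts <- matrix(0L, nrow = length(x), ncol = length(glycan_residues),
                   dimnames = list(NULL, glycan_residues))
  token_re <- "([A-Za-z]+)\\((\\d+)\\)"
  matches <- regmatches(x, gregexpr(token_re, x))
  for (i in seq_along(x)) {
    toks <- matches[[i]]
    consumed <- paste(toks, collapse = "")
    if (length(toks) == 0L || consumed != gsub("[[:space:]]", "", x[i])) {
      stop(sprintf("malformed glycan composition string: '%s'", x[i]))
    }
    nm <- tolower(sub(token_re, "\\1", toks))
    cnt <- as.integer(sub(token_re, "\\2", toks))
    unknown <- setdiff(nm, names(.residue_synonyms))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown residue name '%s' in composition '%s'",
                   unknown[1L], x[i]))
    }
    key <- .residue_synonyms[nm]
    for (j in seq_along(key)) {
      counts[i, key[j]] <- counts[i, key[j]] + cnt[j]
    }
  }
  as.data.frame(counts)
}

#' Format glycan compositions as canonical strings
#'
#' Inverse of [parse_composition()]: writes residues in canonical order,
#' omitting zero counts, so `parse_composition(format_composition(x))`
#' round-trips.
#'
#' @param comp Data frame of residue counts (columns as [glycan_residues]).
#' @return Character vector of composition strings.
#' @export
format_composition <- function(comp) {
  comp <- validate_composition(comp, allow_zero = TRUE)
  vapply(seq_len(nrow(comp)), function(i) {
    cnt <- as.integer(comp[i, glycan_residues])
    keep <- cnt > 0L
    paste0(.residue_display[glycan_residues[keep]], "(", cnt[keep], ")",
           collapse = "")
  }, character(1))
}

# Coerce/validate a residue-count table; fills missing residue columns with 0.
validate_composition <- function(comp, allow_zero = FALSE) {
  if (is.character(comp)) comp <- parse_composition(comp)
  comp <- as.data.frame(comp)
  missing_cols <- setdiff(glycan_residues, names(comp))
  for (m in missing_cols) comp[[m]] <- 0L
  comp <- comp[, glycan_residues, drop = FALSE]
  cm <- as.matrix(comp)
  if (any(is.na(cm)) || any(cm < 0) || any(cm != round(cm))) {
    stop("glycan residue counts must be non-negative integers")
  }
  if (!allow_zero && nrow(comp) > 0L && any(rowSums(cm) == 0)) {
    stop("invalid glycan: all residue counts are zero")
  }
  comp
}

#' Monoisotopic glycan mass
#'
#' Sum of residue counts times standard monoisotopic residue masses.
#'
#' @param comp Composition table (or character vector of composition strings).
#' @return Numeric vector of masses in Da.
#' @examples
#' glycan_mass("HexNAc(2)Hex(3)") # 892.3172
#' @export
glycan_mass <- function(comp) {
  comp <- validate_composition(comp, allow_zero = TRUE)
  as.numeric(as.matrix(comp) %*% .residue_masses[glycan_residues])
}

#' Hierarchical N-glycan classification
#'
#' Assigns each composition to exactly one of seven classes, first match
#' wins: (1) phospho; (2) sialylated (any NeuAc/NeuGc); (3) fucosylated;
#' (4) high mannose (HexNAc(2) core with 4-12 Hex, nothing else);
#' (5) paucimannose (HexNAc(2) core with 1-3 Hex, nothing else);
#' (6) small (fewer than three HexNAc only); (7) complex/hybrid (remainder).
#' A glycan that is both sialylated and fucosylated is therefore counted as
#' sialylated only.
#'
#' @param comp Composition table or character vector.
#' @return Factor with levels [n_glycan_classes].
#' @export
classify_n <- function(comp) {
  comp <- validate_composition(comp)
  sia <- comp$neuac + comp$neugc
  clean <- comp$sulfo == 0L  # phospho/sia/fuc already consumed by hierarchy
  cls <- ifelse(comp$phospho > 0L, "phospho",
         ifelse(sia > 0L, "sialylated",
         ifelse(comp$fuc > 0L, "fucosylated",
         ifelse(clean & comp$hexnac == 2L & comp$hex >= 4L & comp$hex <= 12L,
                "high_mannose",
         ifelse(clean & comp$hexnac == 2L & comp$hex >= 1L & comp$hex <= 3L,
                "paucimannose",
         ifelse(clean & comp$hexnac < 3L & comp$hex == 0L, "small",
                "complex_hybrid"))))))
  factor(cls, levels = n_glycan_classes)
}

#' Hierarchical O-glycan classification
#'
#' First match wins: (1) O-phospho; (2) O-sialylated; (3) O-fucosylated;
#' (4) O-sulfated; (5) O-GlcNAc (a single HexNAc and nothing else);
#' (6) O-hexose (fewer than three HexNAc with at least one Hex, nothing
#' else); (7) O-hybrid (remainder).
#'
#' @inheritParams classify_n
#' @return Factor with levels [o_glycan_classes].
#' @export
classify_o <- function(comp) {
  comp <- validate_composition(comp)
  sia <- comp$neuac + comp$neugc
  cls <- ifelse(comp$phospho > 0L, "o_phospho",
         ifelse(sia > 0L, "o_sialylated",
         ifelse(comp$fuc > 0L, "o_fucosylated",
         ifelse(comp$sulfo > 0L, "o_sulfated",
         ifelse(comp$hexnac == 1L & comp$hex == 0L, "o_glcnac",
         ifelse(comp$hexnac < 3L & comp$hex >= 1L, "o_hexose",
                "o_hybrid"))))))
  factor(cls, levels = o_glycan_classes)
}

#' Composition-database filtering rules
#'
#' Evaluates the three plausibility rules used to filter open-search N-glycan
#' composition databases:
#' rule 1: HexNAc count at most `2 * Hex + 1`;
#' rule 2: NeuAc+NeuGc at most `Hex/2 + 1` and Fuc at most `Hex/2 + 1`
#' (real-valued division);
#' rule 3: NeuAc+NeuGc+Fuc at most 5.
#' An entry is retained iff all three hold. Entries are de-duplicated by
#' canonical composition string.
#'
#' @param entries Composition table or character vector of composition
#'   strings.
#' @return Data frame with one row per unique composition: the canonical
#'   `composition` string, residue counts, `mass`, logical `rule1_pass`,
#'   `rule2_pass`, `rule3_pass` and `retained`.
#' @examples
#' filter_database(c("HexNAc(2)Hex(5)", "HexNAc(6)Hex(2)"))
#' @export
filter_database <- function(entries) {
  comp <- validate_composition(entries, allow_zero = TRUE)
  key <- format_composition(comp)
  keep <- !duplicated(key)
  comp <- comp[keep, , drop = FALSE]
  key <- key[keep]
  sia <- comp$neuac + comp$neugc
  out <- data.frame(composition = key, comp,
                    mass = glycan_mass(comp),
                    rule1_pass = comp$hexnac <= 2 * comp$hex + 1,
                    rule2_pass = sia <= comp$hex / 2 + 1 &
                                 comp$fuc <= comp$hex / 2 + 1,
                    rule3_pass = sia + comp$fuc <= 5,
                    stringsAsFactors = FALSE)
  out$retained <- out$rule1_pass & out$rule2_pass & out$rule3_pass
  rownames(out) <- NULL
  out
}

#' Read a glycan composition database file
#'
#' Plain-text list with one composition string per line, or a tab-separated
#' table whose first column holds composition strings (an optional second
#' column with masses is ignored; masses are recomputed).
#'
#' @param path File path.
#' @return Character vector of composition strings.
#' @export
read_glycan_database <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && grepl("\t", lines[1L])) {
    first <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
    if (grepl("composition", tolower(first[1L]))) first <- first[-1L]
    lines <- first
  }
  lines
}

#' Write a glycan classification table
#'
#' Tab-separated table with composition, mode, class, mass and the database
#' rule flags, re-readable with [utils::read.delim()].
#'
#' @param entries Composition table or character vector.
#' @param path Output file path.
#' @param mode `"N"` or `"O"`: which classification hierarchy to apply.
#' @return The written table, invisibly.
#' @export
write_glycan_classification <- function(entries, path, mode = c("N", "O")) {
  mode <- match.arg(mode)
  db <- filter_database(entries)
  db$mode <- mode
  db$class <- as.character(
    if (mode == "N") classify_n(db[, glycan_residues])
    else classify_o(db[, glycan_residues]))
  cols <- c("composition", "mode", "class", "mass",
            "rule1_pass", "rule2_pass", "rule3_pass", "retained")
  utils::write.table(db[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(db)
}
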