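# FASTA and tabular input/output, with residue-alphabet normalization.

#' Normalize residue strings to the 23-letter alphabet
#'
#' Uppercases sequences, remaps the nonstandard residues selenocysteine
#' (`U` to `C`) and pyrrolysine (`O` to `K`), and replaces any remaining
#' character outside the 23-letter alphabet (20 standard residues plus
#' `X`, `B`, `Z`) with `X`. Normalization is idempotent.
#'
#' @param sequences Character vector of residue strings.
#' @return Character vector of normalized sequences with attribute
#'   `"n_substituted"`, the total number of characters that were remapped
#'   (case changes are not counted as substitutions).
#' @examples
#' normalize_sequences(c("mku", "AC1D"))
#' @export
normalize_sequences <- function(sequences) {
  up <- toupper(sequences)
  out <- chartr("UO", "CK", up)
  n_sub <- sum(nchar(up) - nchar(gsub("[UO]", "", up)))
  bad <- gregexpr(sprintf("[^%s]", paste(PROTEIN_ALPHABET, collapse = "")), out)
  n_bad <- sum(vapply(bad, function(m) if (m[1L] == -1L) 0L else length(m),
                      integer(1)))
  if (n_bad > 0) {
    out <- gsub(sprintf("[^%s]", paste(PROTEIN_ALPHABET, collapse = "")), "X",
                out)
  }
  structure(out, n_substituted = n_sub + n_bad)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are normalized to the 23-letter alphabet (see
#' [normalize_sequences()]): uppercased, `U` mapped to `C`, `O` to `K`,
#' anything else outside the alphabet to `X`. Header text after the first
#' whitespace is kept as the description and never used as an identifier.
#'
#' @param path Path to a FASTA file. Multi-line (wrapped) sequences are
#'   accepted.
#' @return A `data.frame` with columns `id`, `description` and `sequence`,
#'   one row per record in file order, carrying attribute `"n_substituted"`
#'   with the number of remapped characters.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stopf("empty sequence for record(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  seqs <- normalize_sequences(seqs)
  out <- data.frame(id = ids, description = descs,
                    sequence = as.character(seqs),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_substituted") <- attr(seqs, "n_substituted")
  out
}

#' Write protein records to a FASTA file
#'
#' Sequences are wrapped at 60 columns. Reading the file back with
#' [read_fasta()] reproduces ids and sequences exactly.
#'
#' @param records A `data.frame` with columns `id` and `sequence`
#'   (optionally `description`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a label table
#'
#' Reads a tab-separated table with columns `id`, `level1` (`pos` or
#' `neg`) and, for positives only, `level2` (the enzyme class). The
#' hierarchy contract is enforced: every positive row must carry a class
#' and no negative row may.
#'
#' @param path Path to a headerless 2- or 3-column TSV file.
#' @return A `data.frame` with columns `id`, `level1` (`"pos"`/`"neg"`)
#'   and `level2` (class name, `NA` for negatives).
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stopf("label table not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld < 2L | nfld > 3L)) {
    stopf("label table rows must have 2 or 3 tab-separated fields (row %d has %d)",
          which(nfld < 2L | nfld > 3L)[1L], nfld[nfld < 2L | nfld > 3L][1L])
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  lvl1 <- vapply(parts, `[[`, character(1), 2L)
  lvl2 <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_,
                 character(1))
  lvl2[!is.na(lvl2) & !nzchar(lvl2)] <- NA_character_
  if (any(!lvl1 %in% c("pos", "neg"))) {
    stopf("unknown level-1 label '%s' for id '%s' (expected 'pos' or 'neg')",
          lvl1[!lvl1 %in% c("pos", "neg")][1L], ids[!lvl1 %in% c("pos", "neg")][1L])
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate id(s) in label table: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  miss <- lvl1 == "pos" & is.na(lvl2)
  if (any(miss)) {
    stopf("positive example '%s' lacks a level-2 class", ids[miss][1L])
  }
  extra <- lvl1 == "neg" & !is.na(lvl2)
  if (any(extra)) {
    stopf("negative example '%s' must not carry a level-2 class", ids[extra][1L])
  }
  data.frame(id = ids, level1 = lvl1, level2 = lvl2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a label table
#'
#' Inverse of [read_label_table()]: writes `id`, `level1` and (for
#' positives) `level2` as a headerless TSV.
#'
#' @param labels A `data.frame` with columns `id`, `level1`, `level2`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_table <- function(labels, path) {
  stopifnot(all(c("id", "level1") %in% names(labels)))
  lvl2 <- labels$level2 %||% rep(NA_character_, nrow(labels))
  lines <- ifelse(is.na(lvl2),
                  paste(labels$id, labels$level1, sep = "\t"),
                  paste(labels$id, labels$level1, lvl2, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Serialize a named probability vector as "class=p;class=p" with a fixed
# number of significant digits so identical predictions give identical bytes.
#' @noRd
format_prob_string <- function(p) {
  if (length(p) == 0L || all(is.na(p))) return("")
  paste(sprintf("%s=%.10g", names(p), p), collapse = ";")
}

#' Write hierarchical predictions to TSV
#'
#' Writes one row per prediction with deterministic column order:
#' `id`, `level1_decision`, `level1_votes` (the three component votes as
#' `cnn|ffnn|gbt`), `level2_class` and `level2_probabilities`
#' (`class=prob` pairs joined by `;`). Gate-rejected records carry the
#' sentinel `"non-ROSes"` and an empty probability field.
#'
#' @param predictions A prediction `data.frame` as returned by
#'   [predict.ros_classifier()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("id", "level1_decision", "level1_votes", "level2_class",
            "level2_probabilities")
  stopifnot(all(cols %in% names(predictions)))
  header <- paste(cols, collapse = "\t")
  body <- do.call(paste, c(unname(predictions[cols]), list(sep = "\t")))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return A `data.frame` with the five prediction columns.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stopf("prediction file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = character(0))
}
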