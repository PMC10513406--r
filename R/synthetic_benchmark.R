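# Synthetic benchmark generator: motif-defined enzyme families of
# unequal size, uniform random background negatives, and near-positive
# hard negatives carrying a truncated (half-length) family motif. The
# generated data has the statistical structure the classifier assumes —
# class-specific sequence signal on a feature-poor background — and is a
# pure function of its specification (including the seed).

#' Default motif set of the synthetic benchmark
#'
#' Five length-8 motifs, pairwise distinct (and therefore pairwise
#' non-substring) and well separated in composition, one per emulated
#' enzyme family.
#'
#' @return Named character vector of motifs.
#' @export
default_motifs <- function() {
  c(catalase                = "HWDKCEYF",
    superoxide_dismutase    = "WMHNKDGC",
    thioredoxin_reductase   = "CPYCKRHE",
    glutathione_peroxidase  = "YWGKQCDN",
    cytochrome_c_peroxidase = "KHFWEDTM")
}

#' Specification of a synthetic benchmark dataset
#'
#' The defaults define the package's reference benchmark: 5 enzyme
#' families with unequal sizes summing to 340 positives, 1.8 negatives
#' per positive, sequence lengths 80-200, a 5% per-residue substitution
#' rate on implanted motifs, and 30% of negatives being hard negatives.
#'
#' @param n_classes Number of positive families (>= 2).
#' @param class_sizes Positive count per family (may be unequal).
#' @param motifs One distinct residue motif (length >= 5) per family;
#'   motifs must not be substrings of one another. Named entries give
#'   the class names.
#' @param seq_length_range Min/max sequence length; the minimum must be
#'   at least the longest motif.
#' @param mutation_rate Per-residue substitution probability in `[0, 1)`
#'   applied to the implanted motif.
#' @param negative_ratio Negatives generated per positive.
#' @param hard_negative_fraction Share of negatives that carry the
#'   first half of a randomly chosen family motif.
#' @param seed Integer seed; generation is fully determined by the spec
#'   including this seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 5L,
                           class_sizes = c(100L, 80L, 60L, 60L, 40L),
                           motifs = default_motifs(),
                           seq_length_range = c(80L, 200L),
                           mutation_rate = 0.05,
                           negative_ratio = 1.8,
                           hard_negative_fraction = 0.3,
                           seed = 42L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  if (length(class_sizes) != n_classes && length(motifs) == length(class_sizes)) {
    n_classes <- length(class_sizes)   # sizes+motifs agree; follow them
  }
  if (length(class_sizes) != n_classes || any(class_sizes < 1L)) {
    stopf("class_sizes must give a positive count for each of the %d classes",
          n_classes)
  }
  motifs <- motifs[seq_len(n_classes)]
  if (anyNA(motifs) || length(motifs) != n_classes) {
    stopf("one motif per class is required")
  }
  if (is.null(names(motifs))) names(motifs) <- sprintf("class%d", seq_len(n_classes))
  if (anyDuplicated(motifs)) stopf("motifs must be pairwise distinct")
  if (any(nchar(motifs) < 5L)) stopf("motifs must be at least 5 residues long")
  for (i in seq_along(motifs)) {
    for (j in seq_along(motifs)) {
      if (i != j && grepl(motifs[i], motifs[j], fixed = TRUE)) {
        stopf("motif '%s' is a substring of motif '%s'", motifs[i], motifs[j])
      }
    }
  }
  if (length(seq_length_range) != 2L || seq_length_range[1L] > seq_length_range[2L]) {
    stopf("seq_length_range must be c(min, max) with min <= max")
  }
  if (seq_length_range[1L] < max(nchar(motifs))) {
    stopf("minimum sequence length (%d) must cover the longest motif (%d)",
          seq_length_range[1L], max(nchar(motifs)))
  }
  if (mutation_rate < 0 || mutation_rate >= 1) stopf("mutation_rate must be in [0, 1)")
  if (negative_ratio < 0) stopf("negative_ratio must be non-negative")
  if (hard_negative_fraction < 0 || hard_negative_fraction > 1) {
    stopf("hard_negative_fraction must be in [0, 1]")
  }
  structure(list(n_classes = n_classes,
                 class_sizes = as.integer(class_sizes),
                 motifs = motifs,
                 seq_length_range = as.integer(seq_length_range),
                 mutation_rate = mutation_rate,
                 negative_ratio = negative_ratio,
                 hard_negative_fraction = hard_negative_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @noRd
random_background <- function(len) {
  paste(sample(STANDARD_RESIDUES, len, replace = TRUE), collapse = "")
}

#' Randomly substitute residues in a sequence
#'
#' Each position is independently replaced, with probability `rate`, by
#' a residue drawn uniformly from the other 19 standard residues; the
#' length is preserved.
#'
#' @param sequence Residue string.
#' @param rate Substitution probability in `[0, 1)`.
#' @param seed Optional integer seed; `NULL` uses (and advances) the
#'   current RNG state.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(sequence, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  run <- function() {
    ch <- seq_chars(sequence)[[1L]]
    hit <- stats::runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(a) {
        sample(setdiff(STANDARD_RESIDUES, a), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Implant `insert` at a uniform-random position of a fresh uniform
# background of length `len` (replacing, not inserting, residues).
#' @noRd
implant <- function(insert, len) {
  bg <- random_background(len)
  pos <- sample.int(len - nchar(insert) + 1L, 1L)
  paste0(substr(bg, 1L, pos - 1L), insert,
         substr(bg, pos + nchar(insert), len))
}

#' Generate one motif-defined synthetic family
#'
#' Each record is a uniform random background of sampled length with the
#' family motif — mutated at the given per-residue rate — implanted at a
#' uniform random position. At rate 0 every record contains the exact
#' motif as a substring.
#'
#' @param motif Family motif.
#' @param n Number of records.
#' @param length_range Min/max sequence length.
#' @param mutation_rate Per-residue substitution probability for the
#'   implanted motif copy.
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for record ids.
#' @return Records `data.frame` (`id`, `description`, `sequence`).
#' @export
generate_family <- function(motif, n, length_range = c(80L, 200L),
                            mutation_rate = 0, seed = NULL,
                            id_prefix = "fam") {
  if (!is_count(n)) stopf("n must be a non-negative count")
  if (length_range[1L] < nchar(motif)) {
    stopf("minimum length (%d) is shorter than the motif (%d)",
          length_range[1L], nchar(motif))
  }
  run <- function() {
    seqs <- character(n)
    for (i in seq_len(n)) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      seqs[i] <- implant(mutate_sequence(motif, mutation_rate), len)
    }
    data.frame(id = if (n > 0L) sprintf("%s_%04d", id_prefix, seq_len(n)) else character(0),
               description = character(n), sequence = seqs,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a labeled synthetic benchmark dataset
#'
#' Produces `sum(class_sizes)` positives labeled with their family,
#' plus `round(negative_ratio * positives)` negatives, of which
#' `round(hard_negative_fraction * negatives)` are hard negatives
#' carrying the first half of a randomly chosen family motif and the
#' rest are pure uniform background. Fully determined by the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return Labeled examples `data.frame` with columns `id`,
#'   `description`, `sequence`, `level1` (`"pos"`/`"neg"`) and `level2`
#'   (family name, `NA` for negatives), with the spec attached as
#'   attribute `"spec"`.
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_pos <- sum(spec$class_sizes)
  n_neg <- round(spec$negative_ratio * n_pos)
  n_hard <- round(spec$hard_negative_fraction * n_neg)
  classes <- names(spec$motifs)
  with_seed(spec$seed, {
    pos <- vector("list", spec$n_classes)
    for (ci in seq_len(spec$n_classes)) {
      fam <- generate_family(spec$motifs[[ci]], spec$class_sizes[ci],
                             spec$seq_length_range, spec$mutation_rate,
                             seed = NULL, id_prefix = classes[ci])
      fam$level1 <- "pos"
      fam$level2 <- classes[ci]
      fam$description <- sprintf("synthetic %s family member", classes[ci])
      pos[[ci]] <- fam
    }
    neg_seqs <- character(n_neg)
    neg_desc <- character(n_neg)
    for (i in seq_len(n_neg)) {
      len <- sample(spec$seq_length_range[1L]:spec$seq_length_range[2L], 1L)
      if (i <= n_hard) {
        motif <- spec$motifs[[sample.int(spec$n_classes, 1L)]]
        half <- substr(motif, 1L, nchar(motif) %/% 2L)
        neg_seqs[i] <- implant(half, len)
        neg_desc[i] <- "synthetic hard negative (half motif)"
      } else {
        neg_seqs[i] <- random_background(len)
        neg_desc[i] <- "synthetic background negative"
      }
    }
    neg <- data.frame(id = if (n_neg > 0L) sprintf("neg_%04d", seq_len(n_neg)) else character(0),
                      description = neg_desc, sequence = neg_seqs,
                      level1 = rep("neg", n_neg),
                      level2 = rep(NA_character_, n_neg),
                      stringsAsFactors = FALSE)
    out <- rbind(do.call(rbind, pos), neg)
    rownames(out) <- NULL
    attr(out, "spec") <- spec
    out
  })
}
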