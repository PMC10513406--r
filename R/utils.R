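# Internal helpers shared across the package.

# 20 standard residues, alphabetical
STANDARD_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                       "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 23-letter working alphabet: the 20 standard residues plus
# X (unknown), B (Asn/Asp) and Z (Gln/Glu)
AMBIGUOUS_RESIDUES <- c("X", "B", "Z")
PROTEIN_ALPHABET <- c(STANDARD_RESIDUES, AMBIGUOUS_RESIDUES)

# Sentinel emitted for sequences rejected by the level-1 gate
NON_ROSES_SENTINEL <- "non-ROSes"

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls never perturb user RNG streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Split residue strings into single-character vectors
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)
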