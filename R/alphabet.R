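#' Amino-acid alphabet
#'
#' The canonical 20-letter amino-acid alphabet used throughout the package,
#' in fixed alphabetical one-letter order. Every sequence distribution
#' (`L x 20` matrix) uses this column order; it is exported so that external
#' predictor adapters can match it.
#'
#' @format A character vector of 20 one-letter codes.
#' @export
aa_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# three-letter codes for PDB output, same order as aa_alphabet
aa_three <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR", X = "UNK"
)

aa_one <- stats::setNames(names(aa_three), aa_three)

#' Default mutation alphabet
#'
#' The alphabet optimizers draw proposals from. Cysteine is excluded by
#' default, the common de novo design practice that avoids spurious
#' disulfides; pass `exclude = character()` to allow all 20 letters.
#'
#' @param exclude Letters to drop from [aa_alphabet].
#' @return Character vector of allowed letters.
#' @export
mutation_alphabet <- function(exclude = "C") {
  setdiff(aa_alphabet, exclude)
}

#' Convert a sequence to a one-hot sequence distribution
#'
#' @param seq Character vector of single letters, or a single string.
#' @return `L x 20` matrix with one-hot rows, columns ordered as
#'   [aa_alphabet].
#' @export
one_hot_sequence <- function(seq) {
  seq <- split_sequence(seq)
  idx <- match(seq, aa_alphabet)
  if (anyNA(idx)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(seq[is.na(idx)]), collapse = ", "))
  }
  P <- matrix(0, nrow = length(seq), ncol = 20,
              dimnames = list(NULL, aa_alphabet))
  P[cbind(seq_along(idx), idx)] <- 1
  P
}

#' Argmax decoding of a sequence distribution
#'
#' @param P `L x 20` sequence distribution matrix.
#' @return Character vector of length L (ties broken toward the earlier
#'   letter in [aa_alphabet]).
#' @export
argmax_sequence <- function(P) {
  stopifnot(is.matrix(P), ncol(P) == 20)
  aa_alphabet[max.col(P, ties.method = "first")]
}

split_sequence <- function(seq) {
  if (length(seq) == 1 && nchar(seq) > 1) seq <- strsplit(seq, "")[[1]]
  as.character(seq)
}

collapse_sequence <- function(seq) paste(seq, collapse = "")

check_sequence_distribution <- function(P, tol = 1e-3) {
  stopifnot(is.matrix(P), ncol(P) == 20, all(is.finite(P)))
  if (any(P < -tol) || any(P > 1 + tol)) {
    stop("sequence distribution entries must lie in [0, 1]")
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    stop("sequence distribution rows must sum to 1 (max deviation ",
         signif(max(abs(rs - 1)), 3), ")")
  }
  invisible(P)
}

# run expr with a private RNG state seeded at `seed`; the global RNG stream
# is untouched (no global RNG state is ever consumed by package code)
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' Sample a random sequence
#'
#' @param n Number of residues.
#' @param seed Integer seed; the global RNG stream is not touched.
#' @param alphabet Letters to sample from (default [mutation_alphabet]).
#' @return Character vector of length `n`.
#' @export
random_sequence <- function(n, seed, alphabet = mutation_alphabet()) {
  with_seed(seed, sample(alphabet, n, replace = TRUE))
}
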