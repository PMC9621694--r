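#' Backbone structure
#'
#' A backbone structure is a tibble with one row per residue and matrix
#' columns holding the backbone atom coordinates, so it chains directly with
#' dplyr verbs:
#'
#' * `chain` — single-letter chain identifier
#' * `resno` — 1-based residue number (file convention), strictly
#'   increasing within a chain
#' * `aa`    — one-letter amino-acid code (or `"X"` for unknown)
#' * `N`, `CA`, `C` — `L x 3` matrix columns of coordinates in Angstrom
#'
#' All of N, CA and C must be present and finite for every residue;
#' ingest ([read_structure]) drops residues that are missing any of them.
#' Virtual C-beta positions are always recomputed from N/CA/C (see
#' [virtual_cb]) rather than stored, so glycine and mutated positions are
#' handled uniformly.
#'
#' @param chain Character vector of chain ids (recycled if length 1).
#' @param resno Integer residue numbers.
#' @param aa Character vector of one-letter codes (recycled if length 1).
#' @param N,CA,C `L x 3` coordinate matrices.
#' @return A `backbone` tibble.
#' @export
backbone <- function(chain, resno, aa, N, CA, C) {
  L <- length(resno)
  chain <- rep_len(as.character(chain), L)
  aa <- rep_len(split_sequence(aa), L)
  N <- as_coord_matrix(N, L); CA <- as_coord_matrix(CA, L)
  C <- as_coord_matrix(C, L)
  x <- tibble::tibble(chain = chain, resno = as.integer(resno), aa = aa,
                      N = N, CA = CA, C = C)
  x <- tibble::new_tibble(x, class = "backbone")
  validate_backbone(x)
}

as_coord_matrix <- function(m, L) {
  m <- as.matrix(m)
  if (ncol(m) != 3 || nrow(m) != L) stop("coordinates must be an L x 3 matrix")
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

validate_backbone <- function(x) {
  stopifnot(all(c("chain", "resno", "aa", "N", "CA", "C") %in% names(x)))
  for (atom in c("N", "CA", "C")) {
    if (!all(is.finite(x[[atom]]))) stop("non-finite ", atom, " coordinates")
  }
  if (any(x$resno < 0, na.rm = TRUE)) {
    stop("negative residue numbers are not supported")
  }
  bad <- unlist(lapply(split(x$resno, x$chain), function(r) any(diff(r) <= 0)))
  if (any(bad)) {
    stop("residue numbers must be strictly increasing within chain(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  x
}

#' @export
print.backbone <- function(x, ...) {
  cat("<backbone> ", nrow(x), " residues, ",
      length(unique(x$chain)), " chain(s) [",
      paste(unique(x$chain), collapse = ","), "]\n", sep = "")
  NextMethod()
}

n_residues <- function(x) nrow(x)

#' Extract the amino-acid sequence of a structure
#'
#' @param x A [backbone] structure.
#' @param collapse Return a single string instead of a letter vector.
#' @return Character vector (or string) of one-letter codes.
#' @export
structure_sequence <- function(x, collapse = FALSE) {
  if (collapse) collapse_sequence(x$aa) else x$aa
}

#' Flatten backbone atoms to a point matrix
#'
#' Interleaves the selected atoms per residue (residue-major order), the
#' layout used for superposition and RMSD.
#'
#' @param x A [backbone] structure.
#' @param atoms Which atoms to include, in order.
#' @param rows Optional residue index subset (0-based indices are not
#'   accepted; these are row positions, not file residue numbers).
#' @return `(length(rows) * length(atoms)) x 3` matrix.
#' @export
backbone_coords <- function(x, atoms = c("N", "CA", "C"), rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x))
  stopifnot(all(atoms %in% c("N", "CA", "C")))
  mats <- lapply(atoms, function(a) x[[a]][rows, , drop = FALSE])
  out <- matrix(0, nrow = length(rows) * length(atoms), ncol = 3)
  for (k in seq_along(atoms)) {
    out[seq(k, by = length(atoms), length.out = length(rows)), ] <- mats[[k]]
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Apply a rigid transform to a structure or point set
#'
#' @param x A [backbone] structure or an `n x 3` matrix.
#' @param rotation `3 x 3` rotation matrix.
#' @param translation Length-3 translation vector.
#' @return Object of the same type with transformed coordinates.
#' @export
transform_structure <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  if (is.matrix(x)) {
    return(sweep(x %*% t(rotation), 2, translation, "+"))
  }
  for (atom in c("N", "CA", "C")) {
    x[[atom]] <- sweep(x[[atom]] %*% t(rotation), 2, translation, "+")
  }
  x
}

#' Concatenate structures into a multi-chain complex
#'
#' Rows are stacked in order; chains must not overlap between parts.
#'
#' @param ... [backbone] structures.
#' @return A [backbone] structure.
#' @export
bind_chains <- function(...) {
  parts <- list(...)
  chains <- unlist(lapply(parts, function(p) unique(p$chain)))
  if (anyDuplicated(chains)) stop("duplicate chain ids across parts")
  out <- dplyr::bind_rows(parts)
  validate_backbone(tibble::new_tibble(out, class = "backbone"))
}

# row index of the first residue of the second chain, or NULL for one chain
chain_boundary_of <- function(x) {
  ch <- unique(x$chain)
  if (length(ch) == 1) return(NULL)
  if (length(ch) > 2) stop("more than two chains are not supported here")
  match(ch[2], x$chain)
}
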