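#' Read a backbone structure from a PDB file
#'
#' Parses ATOM records (via bio3d) and keeps residues with a complete
#' N/CA/C backbone; incomplete residues are dropped with a warning.
#' Chains and 1-based residue numbering are preserved. Insertion codes,
#' negative residue numbers, alternate locations beyond the first, and
#' multi-model files are not supported.
#'
#' @param path Path to a PDB-format file.
#' @return A [backbone] structure.
#' @export
read_structure <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no parsable ATOM records in ", path)
  at <- at[at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported")
  }
  if (any(at$resno < 0)) stop("negative residue numbers are not supported")
  key <- paste(at$chain, at$resno, at$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) records: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }

  res_key <- paste(at$chain, at$resno)
  keep_order <- unique(res_key)
  complete <- vapply(keep_order, function(k) {
    all(c("N", "CA", "C") %in% at$elety[res_key == k])
  }, logical(1))
  if (any(!complete)) {
    warning("dropping ", sum(!complete),
            " residue(s) with incomplete backbone: ",
            paste(utils::head(keep_order[!complete], 5), collapse = "; "))
  }
  keep_order <- keep_order[complete]
  if (length(keep_order) == 0) stop("no residues with complete backbone")

  pick <- function(k, atom) {
    row <- at[res_key == k & at$elety == atom, , drop = FALSE][1, ]
    c(row$x, row$y, row$z)
  }
  coords <- lapply(c(N = "N", CA = "CA", C = "C"), function(atom) {
    do.call(rbind, lapply(keep_order, pick, atom = atom))
  })
  first <- match(keep_order, res_key)
  aa <- unname(aa_one[at$resid[first]])
  aa[is.na(aa)] <- "X"
  backbone(chain = at$chain[first], resno = at$resno[first], aa = aa,
           N = coords$N, CA = coords$CA, C = coords$C)
}

#' Write a backbone structure to a PDB file
#'
#' Emits N/CA/C ATOM records. The B-factor column carries a per-residue
#' value when given (the common convention for per-residue confidence,
#' 0-100). Positions whose `mask` entry is TRUE are omitted entirely, which
#' is how masked coordinates of a benchmark record are serialized.
#'
#' @param x A [backbone] structure.
#' @param path Output path.
#' @param bfactor Optional per-residue value for the B-factor column.
#' @param mask Optional logical vector; TRUE positions are not written.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, bfactor = NULL, mask = NULL) {
  L <- nrow(x)
  if (is.null(bfactor)) bfactor <- rep(0, L)
  stopifnot(length(bfactor) == L)
  keep <- if (is.null(mask)) rep(TRUE, L) else !mask
  rows <- which(keep)
  n_at <- length(rows) * 3
  xyz <- backbone_coords(x, rows = rows)            # N, CA, C per residue
  resid <- rep(unname(aa_three[ifelse(x$aa[rows] %in% names(aa_three),
                                      x$aa[rows], "X")]), each = 3)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", n_at),
    resno = rep(x$resno[rows], each = 3),
    resid = resid,
    eleno = seq_len(n_at),
    elety = rep(c("N", "CA", "C"), length(rows)),
    chain = rep(x$chain[rows], each = 3),
    o = rep(1, n_at),
    b = rep(round(bfactor[rows], 2), each = 3)
  )
  invisible(path)
}
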