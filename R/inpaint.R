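#' Generate random mask windows
#'
#' Samples `n_masks` contiguous windows of `mask_length` residues with the
#' start uniform over all valid offsets (with replacement, so duplicate
#' windows are allowed).
#'
#' @param L Protein length.
#' @param mask_length Window length, `<= L`.
#' @param n_masks Number of windows, `>= 1`.
#' @param seed Integer seed.
#' @param channels What the window hides: `"both"` (sequence and
#'   structure, the default), `"sequence"` or `"structure"`.
#' @return Tibble of `mask_window` rows: `start` (0-based), `length`,
#'   `channels`.
#' @export
generate_window_masks <- function(L, mask_length, n_masks, seed = 1,
                                  channels = c("both", "sequence",
                                               "structure")) {
  channels <- match.arg(channels)
  if (mask_length > L) stop("mask_length exceeds protein length")
  stopifnot(mask_length >= 1, n_masks >= 1)
  starts <- with_seed(seed, {
    sample.int(L - mask_length + 1, n_masks, replace = TRUE) - 1L
  })
  tibble::tibble(start = starts, length = as.integer(mask_length),
                 channels = channels)
}

mask_positions <- function(window, L) {
  pos <- (window$start + 1):(window$start + window$length)
  stopifnot(pos[1] >= 1, pos[length(pos)] <= L)
  pos
}

#' Build a masked record
#'
#' Hides a window of a native (structure, sequence) record: masked letters
#' become `"X"` and masked coordinates become `NA` sentinels, so no native
#' information survives in the masked channels. The native record is kept
#' by the caller for scoring only.
#'
#' @param structure Native [backbone] structure.
#' @param sequence Native sequence (defaults to the structure's).
#' @param window One row of [generate_window_masks].
#' @return A `masked_record`: list with `sequence`, `structure` (masked
#'   coordinates `NA`), `window`, and `masked` (logical vector).
#' @export
mask_record <- function(structure, window, sequence = NULL) {
  L <- nrow(structure)
  sequence <- split_sequence(sequence %||% structure_sequence(structure))
  stopifnot(length(sequence) == L)
  pos <- mask_positions(window, L)
  masked <- seq_len(L) %in% pos
  seq_out <- sequence
  str_out <- structure
  if (window$channels %in% c("both", "sequence")) seq_out[masked] <- "X"
  if (window$channels %in% c("both", "structure")) {
    for (atom in c("N", "CA", "C")) str_out[[atom]][masked, ] <- NA_real_
  }
  structure(list(sequence = seq_out, structure = str_out,
                 window = window, masked = masked),
            class = "masked_record")
}

#' Fraction of masked letters recovered
#'
#' @param native,completed Equal-length sequences (vectors or strings).
#' @param window A mask-window row.
#' @return Fraction in `[0, 1]` of masked positions whose completed letter
#'   equals the native letter.
#' @export
sequence_recovery <- function(native, completed, window) {
  native <- split_sequence(native); completed <- split_sequence(completed)
  if (length(native) != length(completed)) stop("sequence length mismatch")
  pos <- mask_positions(window, length(native))
  mean(completed[pos] == native[pos])
}

#' RMSD of the unmasked ("motif") region
#'
#' Kabsch-superposed backbone RMSD over the residues outside the mask
#' window: how much a completion disturbed the part of the protein it was
#' told to keep.
#'
#' @param native,completed Equal-length [backbone] structures.
#' @param window A mask-window row.
#' @param atoms Backbone atoms used.
#' @return RMSD in Angstrom.
#' @export
fixed_region_rmsd <- function(native, completed, window,
                              atoms = c("N", "CA", "C")) {
  if (nrow(native) != nrow(completed)) stop("structure length mismatch")
  pos <- mask_positions(window, nrow(native))
  keep <- setdiff(seq_len(nrow(native)), pos)
  if (length(keep) < 3) stop("fewer than 3 unmasked residues")
  kabsch_superpose(backbone_coords(completed, atoms, keep),
                   backbone_coords(native, atoms, keep))$rmsd
}

#' Completer baselines
#'
#' A completer is any function mapping a `masked_record` to a full-length
#' record `list(structure, sequence)` of the same length -- the contract a
#' trained inpainting network would implement. Two reference completers
#' ship with the harness:
#'
#' * `oracle_completer(native, native_seq)` returns the native record,
#'   the fixed point of the benchmark (recovery 1, RMSD 0).
#' * `baseline_completer()` fills masked letters with poly-alanine and
#'   masked coordinates with an ideal helix grafted onto the flanking
#'   residues; unmasked content is passed through.
#'
#' @param native Native [backbone] structure.
#' @param native_seq Native sequence (defaults to the structure's).
#' @return A completer function.
#' @export
oracle_completer <- function(native, native_seq = NULL) {
  native_seq <- split_sequence(native_seq %||% structure_sequence(native))
  function(record) list(structure = native, sequence = native_seq)
}

#' @rdname oracle_completer
#' @export
baseline_completer <- function() {
  function(record) {
    seq <- record$sequence
    seq[seq == "X"] <- "A"
    str <- record$structure
    miss <- which(!stats::complete.cases(str$CA))
    if (length(miss) > 0) {
      t <- fixture_torsions$helix
      coords <- build_backbone_coords(rep(t["phi"], length(miss)),
                                      rep(t["psi"], length(miss)))
      anchor <- min(miss) - 1
      shift <- if (anchor >= 1) str$C[anchor, ] + c(1.3, 0, 0) else c(0, 0, 0)
      for (atom in c("N", "CA", "C")) {
        str[[atom]][miss, ] <- sweep(coords[[atom]], 2, shift, "+")
      }
    }
    list(structure = str, sequence = seq)
  }
}

#' Run the masked-region recovery benchmark
#'
#' For each input record, generates `n_masks` random windows of
#' `mask_length`, masks the record, asks the completer to fill the window
#' back in, and scores the completion: fixed-region RMSD (unmasked
#' residues, after superposition), masked-region sequence recovery, and --
#' when the completer reports per-residue confidence -- the mean confidence
#' in the replaced region.
#'
#' @param completer A completer function (see [oracle_completer]); may
#'   return an optional `plddt` element.
#' @param records List of `list(structure, sequence)` records (`sequence`
#'   may be omitted to use the structure's).
#' @param mask_length,n_masks,seed Benchmark protocol parameters.
#' @param channels Passed to [generate_window_masks].
#' @return An `inpaint_benchmark` tibble with one row per (record, mask):
#'   `record`, `mask`, `start`, `length`, `fixed_rmsd`, `seq_recovery`,
#'   `masked_plddt`. Per-record averages via [summarise_benchmark].
#' @export
run_benchmark <- function(completer, records, mask_length = 30, n_masks = 20,
                          seed = 1, channels = "both") {
  rows <- list()
  for (r in seq_along(records)) {
    rec <- records[[r]]
    native <- rec$structure
    native_seq <- split_sequence(rec$sequence %||%
                                   structure_sequence(native))
    masks <- generate_window_masks(nrow(native), mask_length, n_masks,
                                   seed = seed + r - 1, channels = channels)
    for (m in seq_len(nrow(masks))) {
      window <- masks[m, ]
      masked <- mask_record(native, window, native_seq)
      out <- completer(masked)
      if (length(out$sequence) != nrow(native) ||
          nrow(out$structure) != nrow(native)) {
        stop("completer returned a record of the wrong length")
      }
      pos <- mask_positions(window, nrow(native))
      rows[[length(rows) + 1]] <- tibble::tibble(
        record = r, mask = m, start = window$start, length = window$length,
        fixed_rmsd = fixed_region_rmsd(native, out$structure, window),
        seq_recovery = sequence_recovery(native_seq, out$sequence, window),
        masked_plddt = if (is.null(out$plddt)) NA_real_
                       else mean(out$plddt[pos]))
    }
  }
  tibble::new_tibble(dplyr::bind_rows(rows), class = "inpaint_benchmark")
}

#' Per-record benchmark averages
#'
#' @param bench An `inpaint_benchmark` table.
#' @return Tibble with one row per record: mean fixed-region RMSD, mean
#'   sequence recovery, mean masked-region confidence, and mask count.
#' @export
summarise_benchmark <- function(bench) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(bench), .data$record),
    n_masks = dplyr::n(),
    fixed_rmsd = mean(.data$fixed_rmsd),
    seq_recovery = mean(.data$seq_recovery),
    masked_plddt = mean(.data$masked_plddt),
    .groups = "drop"
  )
}
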