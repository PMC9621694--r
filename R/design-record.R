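#' Design record
#'
#' The portable unit of provenance for one design: everything needed to
#' reproduce and evaluate it.
#'
#' @param id Design identifier (used in file names and FASTA headers).
#' @param contigs Contig string the design was built from.
#' @param placement The `motif_placement` realized for this design.
#' @param sequence Final designed sequence (letters or string).
#' @param structure Predicted [backbone] structure.
#' @param loss_breakdown Per-term loss tibble (from [composite_loss]).
#' @param metrics One-row tibble of [design_metrics].
#' @param plddt Optional per-residue confidence (written to the PDB
#'   B-factor column).
#' @param provenance Named list: seed, stage configs, tool version, etc.
#' @return A `design_record`.
#' @export
design_record <- function(id, contigs, placement, sequence, structure = NULL,
                          loss_breakdown = NULL, metrics = NULL,
                          plddt = NULL, provenance = list()) {
  provenance$tool_version <- provenance$tool_version %||%
    as.character(utils::packageVersion("motifscaffold"))
  structure(list(id = id, contigs = contigs, placement = placement,
                 sequence = split_sequence(sequence), structure = structure,
                 loss_breakdown = loss_breakdown, metrics = metrics,
                 plddt = plddt, provenance = provenance),
            class = "design_record")
}

#' @export
print.design_record <- function(x, ...) {
  cat("<design_record> ", x$id, " (", x$contigs, "), L = ",
      length(x$sequence), "\n", sep = "")
  invisible(x)
}

#' Write a design record to disk
#'
#' Emits three files under `outdir`: `<id>.pdb` (per-residue confidence in
#' the B-factor column when available), `<id>.fasta` (header carries the
#' design id and contig string) and `<id>.json` (the full record).
#' Re-running with the same record overwrites the same files byte for
#' byte.
#'
#' @param record A [design_record].
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_design <- function(record, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    pdb = file.path(outdir, paste0(record$id, ".pdb")),
    fasta = file.path(outdir, paste0(record$id, ".fasta")),
    json = file.path(outdir, paste0(record$id, ".json"))
  )
  if (!is.null(record$structure)) {
    write_structure(record$structure, paths$pdb, bfactor = record$plddt)
  }
  writeLines(c(paste0(">", record$id, " contigs=", record$contigs),
               collapse_sequence(record$sequence)),
             paths$fasta)
  jsonlite::write_json(record_to_list(record), paths$json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

record_to_list <- function(record) {
  list(
    id = record$id,
    contigs = record$contigs,
    placement = placement_to_list(record$placement),
    sequence = collapse_sequence(record$sequence),
    loss_breakdown = record$loss_breakdown,
    metrics = record$metrics,
    plddt = record$plddt,
    provenance = record$provenance
  )
}

#' Read a design record back from its JSON file
#'
#' Round-trips everything [write_design] serialized (the structure itself
#' lives in the sibling PDB file).
#'
#' @param path Path to a `<id>.json` file written by [write_design].
#' @return A [design_record] (without the structure).
#' @export
read_design <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  placement <- structure(list(
    total_length = raw$placement$total_length,
    motif_mask = raw$placement$motif_mask,
    index_map = tibble::as_tibble(raw$placement$index_map),
    gap_lengths = raw$placement$gap_lengths,
    spec = parse_contigs(raw$placement$contigs)
  ), class = "motif_placement")
  design_record(
    id = raw$id, contigs = raw$contigs, placement = placement,
    sequence = raw$sequence,
    loss_breakdown = if (!is.null(raw$loss_breakdown))
      tibble::as_tibble(raw$loss_breakdown),
    metrics = if (!is.null(raw$metrics)) tibble::as_tibble(raw$metrics),
    plddt = raw$plddt,
    provenance = raw$provenance
  )
}
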