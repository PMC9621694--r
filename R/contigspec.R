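#' Parse a contig specification string
#'
#' A contig string is a comma-separated list of tokens describing, in
#' order, the layout of a design: motif segments and scaffold gaps.
#'
#' * `"A163-181"` — a motif segment: chain A, residues 163 to 181 of the
#'   source structure (1-based, inclusive, so 19 residues)
#' * `"A42"` — a single-residue motif segment
#' * `"5"` — a fixed gap of 5 scaffolded residues
#' * `"10-25"` — a gap whose length is sampled uniformly from 10..25
#'
#' @param spec Non-empty contig string, e.g. `"5,A163-181,10-25"`.
#' @return A `contig_spec`: tibble with columns `kind` (`"motif"`/`"gap"`),
#'   `chain`, `start`, `end` (motif rows), `min_len`, `max_len` (gap rows)
#'   and `length` (motif segment length).
#' @export
parse_contigs <- function(spec) {
  if (!is.character(spec) || length(spec) != 1 || !nzchar(trimws(spec))) {
    stop("contig spec must be a non-empty string")
  }
  tokens <- trimws(strsplit(spec, ",")[[1]])
  if (any(!nzchar(tokens))) stop("empty token in contig spec")
  rows <- lapply(tokens, parse_contig_token)
  out <- dplyr::bind_rows(rows)
  if (!any(out$kind == "motif")) {
    stop("contig spec must contain at least one motif segment")
  }
  tibble::new_tibble(out, class = "contig_spec")
}

parse_contig_token <- function(tok) {
  if (grepl("^[A-Za-z][0-9]+(-[0-9]+)?$", tok)) {
    chain <- substr(tok, 1, 1)
    nums <- as.integer(strsplit(substr(tok, 2, nchar(tok)), "-")[[1]])
    start <- nums[1]; end <- if (length(nums) == 2) nums[2] else nums[1]
    if (end < start) stop("reversed motif range: ", tok)
    return(tibble::tibble(kind = "motif", chain = chain, start = start,
                          end = end, min_len = NA_integer_,
                          max_len = NA_integer_,
                          length = end - start + 1L))
  }
  if (grepl("^[0-9]+(-[0-9]+)?$", tok)) {
    nums <- as.integer(strsplit(tok, "-")[[1]])
    lo <- nums[1]; hi <- if (length(nums) == 2) nums[2] else nums[1]
    if (hi < lo) stop("reversed gap range: ", tok)
    return(tibble::tibble(kind = "gap", chain = NA_character_,
                          start = NA_integer_, end = NA_integer_,
                          min_len = lo, max_len = hi, length = NA_integer_))
  }
  stop("unrecognized contig token: ", tok)
}

#' Format a contig spec back to its string form
#'
#' `parse_contigs(format_contigs(x))` is the identity.
#'
#' @param spec A `contig_spec`.
#' @return Contig string.
#' @export
format_contigs <- function(spec) {
  toks <- vapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    if (r$kind == "motif") {
      if (r$start == r$end) paste0(r$chain, r$start)
      else paste0(r$chain, r$start, "-", r$end)
    } else {
      if (r$min_len == r$max_len) as.character(r$min_len)
      else paste0(r$min_len, "-", r$max_len)
    }
  }, character(1))
  paste(toks, collapse = ",")
}

#' Total number of motif residues in a contig spec
#'
#' @param spec A `contig_spec`.
#' @return Integer residue count (inclusive 1-based ranges).
#' @export
motif_size <- function(spec) {
  sum(spec$length[spec$kind == "motif"])
}

#' Extract the motif residues from a source structure
#'
#' Pulls the residues named by the spec's motif segments, in token order,
#' with their original coordinates, amino acids and numbering.
#'
#' @param spec A `contig_spec` (or contig string).
#' @param source A [backbone] structure containing every referenced
#'   (chain, residue) pair.
#' @return A [backbone] structure of the motif; the `segment` attribute
#'   gives each residue's segment index, and per-segment native sequences
#'   are in the `segment_sequences` attribute.
#' @export
extract_motif <- function(spec, source) {
  if (is.character(spec)) spec <- parse_contigs(spec)
  segs <- spec[spec$kind == "motif", ]
  rows <- integer(0); seg_id <- integer(0)
  for (i in seq_len(nrow(segs))) {
    want <- segs$start[i]:segs$end[i]
    idx <- match(paste(segs$chain[i], want), paste(source$chain, source$resno))
    if (anyNA(idx)) {
      missing <- want[is.na(idx)][1]
      stop("residue ", segs$chain[i], missing, " not present in source")
    }
    rows <- c(rows, idx); seg_id <- c(seg_id, rep(i, length(idx)))
  }
  motif <- source[rows, ]
  motif <- tibble::new_tibble(motif, class = "backbone")
  attr(motif, "segment") <- seg_id
  attr(motif, "segment_sequences") <-
    vapply(split(motif$aa, seg_id), collapse_sequence, character(1))
  motif
}

#' Sample a motif placement
#'
#' Realizes each gap uniformly over its closed integer interval and lays
#' segments out in token order, producing the design-length layout used by
#' the optimizers.
#'
#' @param spec A `contig_spec` (or contig string).
#' @param seed Integer seed; identical seeds give identical placements.
#' @return A `motif_placement` list: `total_length` L, `motif_mask`
#'   (logical L), `index_map` (tibble: design `position`, `segment`,
#'   `offset` within segment for motif positions), `gap_lengths` (realized
#'   lengths in token order) and the originating `spec`.
#' @export
sample_placement <- function(spec, seed = 1) {
  if (is.character(spec)) spec <- parse_contigs(spec)
  gaps <- which(spec$kind == "gap")
  gap_len <- integer(nrow(spec))
  gap_len[gaps] <- with_seed(seed, {
    vapply(gaps, function(i) {
      if (spec$min_len[i] == spec$max_len[i]) spec$min_len[i]
      else sample(spec$min_len[i]:spec$max_len[i], 1)
    }, integer(1))
  })

  mask <- logical(0); seg <- integer(0); off <- integer(0)
  seg_counter <- 0
  for (i in seq_len(nrow(spec))) {
    if (spec$kind[i] == "motif") {
      seg_counter <- seg_counter + 1
      n <- spec$length[i]
      mask <- c(mask, rep(TRUE, n))
      seg <- c(seg, rep(seg_counter, n)); off <- c(off, seq_len(n))
    } else {
      mask <- c(mask, rep(FALSE, gap_len[i]))
    }
  }
  index_map <- tibble::tibble(position = which(mask), segment = seg,
                              offset = off)
  structure(list(total_length = length(mask), motif_mask = mask,
                 index_map = index_map,
                 gap_lengths = gap_len[gaps], spec = spec),
            class = "motif_placement")
}

#' @export
print.motif_placement <- function(x, ...) {
  cat("<motif_placement> L = ", x$total_length, ", motif residues = ",
      sum(x$motif_mask), " (", format_contigs(x$spec), ")\n", sep = "")
  invisible(x)
}

# serializable form of a placement (JSON-friendly)
placement_to_list <- function(p) {
  list(total_length = p$total_length, motif_mask = p$motif_mask,
       index_map = as.list(p$index_map), gap_lengths = p$gap_lengths,
       contigs = format_contigs(p$spec))
}
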