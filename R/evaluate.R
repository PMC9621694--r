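#' Motif RMSD of a predicted design
#'
#' Kabsch-superposed backbone RMSD between the motif region of a predicted
#' structure (the placement's motif positions) and the native motif. The
#' standard recapitulation accuracy metric for scaffolded sites.
#'
#' @param pred Predicted [backbone] structure of the full design.
#' @param native_motif Native motif [backbone] (token order).
#' @param placement A `motif_placement`.
#' @param atoms Backbone atoms used; `"CA"` alone is also accepted.
#' @return RMSD in Angstrom.
#' @export
motif_rmsd_metric <- function(pred, native_motif, placement,
                              atoms = c("N", "CA", "C")) {
  pos <- placement$index_map$position
  if (length(pos) < 3) stop("motif has fewer than 3 residues")
  if (length(pos) != nrow(native_motif)) {
    stop("placement and native motif disagree on motif size")
  }
  kabsch_superpose(backbone_coords(pred, atoms, pos),
                   backbone_coords(native_motif, atoms))$rmsd
}

#' Mean confidence over a region
#'
#' @param plddt Per-residue confidence vector (0-100).
#' @param mask Logical vector (or integer positions) selecting at least
#'   one residue.
#' @return Arithmetic mean confidence.
#' @export
region_mean_plddt <- function(plddt, mask) {
  sel <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(sel) == 0) stop("empty region mask")
  mean(plddt[sel])
}

#' Inter-chain predicted aligned error
#'
#' Aggregates the pairwise aligned error over both off-diagonal chain
#' blocks (binder rows vs target columns and vice versa) -- the interface
#' confidence gauge used to filter binder designs.
#'
#' @param pae `L x L` PAE matrix in Angstrom.
#' @param chain_boundary Row index of the first residue of the second
#'   chain, `1 < chain_boundary <= L`.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return Inter-PAE in Angstrom.
#' @export
inter_pae <- function(pae, chain_boundary, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  L <- nrow(pae)
  if (is.null(chain_boundary) || chain_boundary <= 1 || chain_boundary > L) {
    stop("chain boundary out of range")
  }
  vals <- pae[interchain_mask(L, chain_boundary)]
  if (aggregate == "mean") mean(vals) else stats::median(vals)
}

#' Target-aligned binder RMSD
#'
#' Superposes the predicted complex onto the reference complex using the
#' target chain only, then measures the binder-chain backbone RMSD without
#' re-superposition: how well the binder is placed relative to its target,
#' not just how well it folds.
#'
#' @param pred,reference Equal-length two-chain [backbone] complexes with
#'   corresponding rows; the target chain is everything from
#'   `chain_boundary` on.
#' @param chain_boundary Row index of the first target-chain residue.
#' @param atoms Backbone atoms used.
#' @return RMSD in Angstrom.
#' @export
target_aligned_rmsd <- function(pred, reference, chain_boundary,
                                atoms = c("N", "CA", "C")) {
  L <- nrow(pred)
  if (nrow(reference) != L) stop("complexes differ in length")
  if (chain_boundary <= 1 || chain_boundary > L) {
    stop("chain boundary out of range")
  }
  target <- chain_boundary:L
  binder <- seq_len(chain_boundary - 1)
  if (length(target) < 3) stop("target chain has fewer than 3 residues")
  fit <- kabsch_superpose(backbone_coords(pred, atoms, target),
                          backbone_coords(reference, atoms, target))
  moved <- transform_structure(backbone_coords(pred, atoms, binder),
                               fit$rotation, fit$translation)
  rmsd(moved, backbone_coords(reference, atoms, binder))
}

#' Filter criteria
#'
#' A tidy set of threshold criteria of the kind used to select designs,
#' e.g. pLDDT > 80 and motif RMSD < 1.4 Angstrom. Comparisons are strict,
#' matching the printed inequalities: boundary-equal values fail.
#'
#' @param ... Named thresholds: `name = c(">", 80)` or `name = c("<", 1.4)`
#'   (threshold coerced to numeric), or a ready-made data frame with
#'   columns `metric`, `comparator`, `threshold`.
#' @return A `filter_criteria` tibble.
#' @examples
#' filter_criteria(plddt = c(">", 80), motif_rmsd = c("<", 1.4))
#' @export
filter_criteria <- function(...) {
  args <- list(...)
  if (length(args) == 0) {
    return(tibble::new_tibble(
      tibble::tibble(metric = character(), comparator = character(),
                     threshold = numeric()),
      class = "filter_criteria"))
  }
  if (length(args) == 1 && is.data.frame(args[[1]])) {
    out <- tibble::as_tibble(args[[1]])
  } else {
    out <- tibble::tibble(
      metric = names(args),
      comparator = unname(vapply(args, function(a) as.character(a[1]),
                                 character(1))),
      threshold = unname(vapply(args, function(a) as.numeric(a[2]),
                                numeric(1)))
    )
  }
  stopifnot(all(out$comparator %in% c("<", ">")),
            all(is.finite(out$threshold)))
  tibble::new_tibble(out, class = "filter_criteria")
}

#' Read filter criteria from YAML
#'
#' The file is a list of `{metric, comparator, threshold}` entries.
#'
#' @param path YAML file.
#' @return A [filter_criteria] tibble.
#' @export
read_filter_criteria <- function(path) {
  raw <- yaml::read_yaml(path)
  filter_criteria(dplyr::bind_rows(lapply(raw, tibble::as_tibble)))
}

#' Apply threshold filters to design metrics
#'
#' A design passes iff every criterion holds (strict inequalities). An
#' empty criteria set passes everything.
#'
#' @param metrics Data frame of designs by metric columns (e.g. `plddt`,
#'   `motif_rmsd`, `inter_pae`, `target_aligned_rmsd`); every criterion's
#'   metric must be present.
#' @param criteria A [filter_criteria] tibble.
#' @return The metrics tibble with one logical `pass_<metric>` column per
#'   criterion and an overall `pass` column; the `summary` attribute holds
#'   the pass/fail counts.
#' @export
filter_designs <- function(metrics, criteria) {
  metrics <- tibble::as_tibble(metrics)
  missing <- setdiff(criteria$metric, names(metrics))
  if (length(missing) > 0) {
    stop("metrics are missing column(s): ", paste(missing, collapse = ", "))
  }
  pass_all <- rep(TRUE, nrow(metrics))
  for (i in seq_len(nrow(criteria))) {
    m <- criteria$metric[i]
    ok <- if (criteria$comparator[i] == ">") {
      metrics[[m]] > criteria$threshold[i]
    } else {
      metrics[[m]] < criteria$threshold[i]
    }
    metrics[[paste0("pass_", m)]] <- ok
    pass_all <- pass_all & ok
  }
  metrics$pass <- pass_all
  attr(metrics, "summary") <- tibble::tibble(
    n = nrow(metrics), n_pass = sum(pass_all), n_fail = sum(!pass_all))
  metrics
}

#' Standard design metrics from a prediction
#'
#' Computes the whole-design mean confidence, motif confidence, motif
#' RMSD, and -- for two-chain predictions -- inter-PAE and target-aligned
#' binder RMSD against a reference complex.
#'
#' @param pred A [prediction_result].
#' @param context A [loss_context] with `placement` and `native_motif`.
#' @param reference Optional reference complex for the target-aligned RMSD.
#' @return One-row tibble of metrics.
#' @export
design_metrics <- function(pred, context, reference = NULL) {
  pos <- context$placement$index_map$position
  out <- tibble::tibble(
    plddt = mean(pred$plddt),
    motif_plddt = region_mean_plddt(pred$plddt, pos),
    motif_rmsd = motif_rmsd_metric(pred$coords, context$native_motif,
                                   context$placement)
  )
  if (!is.null(pred$chain_boundary)) {
    out$inter_pae <- inter_pae(pred$pae, pred$chain_boundary)
    if (!is.null(reference)) {
      out$target_aligned_rmsd <- target_aligned_rmsd(
        pred$coords, reference, pred$chain_boundary)
    }
  }
  out
}
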