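#' Prediction result
#'
#' The contract every design loop consumes, regardless of which predictor
#' produced it:
#'
#' * `coords` — predicted [backbone] structure
#' * `geometry` — probabilistic `pairwise_geometry` (binned distance /
#'   orientation distributions per residue pair)
#' * `plddt` — per-residue confidence on the 0-100 scale
#' * `pae` — `L x L` pairwise aligned error in Angstrom, non-negative
#' * `chain_boundary` — optional row index of the first residue of the
#'   second chain (binder/target splits)
#'
#' @param coords,geometry,plddt,pae,chain_boundary See above.
#' @return A `prediction_result`.
#' @export
prediction_result <- function(coords, geometry, plddt, pae,
                              chain_boundary = NULL) {
  L <- nrow(coords)
  stopifnot(length(plddt) == L, all(plddt >= -1e-9), all(plddt <= 100 + 1e-9),
            is.matrix(pae), all(dim(pae) == L), all(pae >= -1e-9))
  structure(list(coords = coords, geometry = geometry,
                 plddt = pmin(pmax(plddt, 0), 100), pae = pmax(pae, 0),
                 chain_boundary = chain_boundary),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result> L = ", nrow(x$coords),
      ", mean pLDDT = ", round(mean(x$plddt), 1),
      ", mean PAE = ", round(mean(x$pae), 2), " A",
      if (!is.null(x$chain_boundary))
        paste0(", chain boundary at ", x$chain_boundary), "\n", sep = "")
  invisible(x)
}

#' Planted-landscape toy world
#'
#' A synthetic, fully deterministic stand-in for a trained structure
#' predictor, used to verify the design machinery at desk scale. The world
#' hides a target structure `X*` and target sequence `s*`; the closer a
#' query sequence distribution is to `s*` (locally, within a smoothing
#' window), the more confidently the toy predictor "predicts" `X*`'s
#' geometry. Recovery of `s*` by the optimizers is the desk-scale analog of
#' designing sequences that strongly encode their backbones.
#'
#' @param structure Target [backbone] structure `X*`.
#' @param sequence Target sequence `s*` (default: the structure's own).
#' @param window Half-width `w` (residues) of the local agreement window.
#' @param max_pae Error cap in Angstrom (the PAE reported when confidence
#'   is zero).
#' @param bins [geometry_bins] used for the emitted distograms.
#' @return A `planted_landscape`.
#' @export
planted_landscape <- function(structure, sequence = NULL, window = 2,
                              max_pae = 30, bins = geometry_bins()) {
  if (is.null(sequence)) sequence <- structure_sequence(structure)
  sequence <- split_sequence(sequence)
  stopifnot(length(sequence) == nrow(structure), window >= 0, max_pae > 0)
  structure(list(structure = structure, sequence = sequence,
                 window = as.integer(window), max_pae = max_pae,
                 bins = bins,
                 ref_bins = sixd_bins(structure, bins),
                 chain_boundary = chain_boundary_of(structure)),
            class = "planted_landscape")
}

#' @export
print.planted_landscape <- function(x, ...) {
  cat("<planted_landscape> L = ", nrow(x$structure), ", w = ", x$window,
      ", max_pae = ", x$max_pae, " A\n", sep = "")
  invisible(x)
}

# per-chain local mean of m over [i-w, i+w], clipped to chain bounds
window_agreement <- function(m, world) {
  L <- length(m)
  w <- world$window
  bounds <- chain_ranges(world)
  a <- numeric(L)
  for (b in bounds) {
    for (i in b[1]:b[2]) {
      lo <- max(b[1], i - w); hi <- min(b[2], i + w)
      a[i] <- mean(m[lo:hi])
    }
  }
  a
}

chain_ranges <- function(world) {
  L <- nrow(world$structure)
  cb <- world$chain_boundary
  if (is.null(cb)) list(c(1, L)) else list(c(1, cb - 1), c(cb, L))
}

#' Toy predictor forward pass
#'
#' Deterministic closed-form "prediction" on a [planted_landscape]: the
#' per-position match `m_i = P_i(s*_i)` is smoothed into a local agreement
#' `a_i` (mean of `m` over the window, clipped to chain bounds); pair
#' confidence is `c_ij = a_i a_j`; the emitted distogram for pair (i, j) is
#' the mixture `c_ij * onehot(6D features of X*) + (1 - c_ij) * uniform`;
#' predicted coordinates are `X*` itself; `plddt_i = 100 a_i`; and
#' `pae_ij = max_pae * (1 - c_ij)`.
#'
#' @param P `L x 20` sequence distribution (or a hard sequence, lifted to
#'   one-hot).
#' @param world A [planted_landscape] with `|s*| = L`.
#' @return A [prediction_result] whose `geometry` is in compact mixture
#'   form (see [as_dense_geometry]).
#' @export
toy_predict <- function(P, world) {
  if (is.character(P)) P <- one_hot_sequence(P)
  check_sequence_distribution(P)
  L <- nrow(world$structure)
  if (nrow(P) != L) {
    stop("sequence distribution length ", nrow(P),
         " does not match world length ", L)
  }
  m <- P[cbind(seq_len(L), match(world$sequence, aa_alphabet))]
  a <- window_agreement(m, world)
  conf <- outer(a, a)
  geometry <- mixture_geometry(conf, world$ref_bins, world$bins)
  prediction_result(coords = world$structure, geometry = geometry,
                    plddt = 100 * a,
                    pae = world$max_pae * (1 - conf),
                    chain_boundary = world$chain_boundary)
}

#' Wrap a planted landscape as a predictor object
#'
#' A predictor is the one-directional contract the optimizers consume: a
#' `predict(P)` function returning a [prediction_result], plus an optional
#' `gradient(loss, P, context)` capability returning the analytic `L x 20`
#' sensitivity of the composite loss. Real-network adapters only need to
#' implement `predict`.
#'
#' @param world A [planted_landscape].
#' @return A `predictor` object with `predict` and `gradient` functions.
#' @export
toy_predictor <- function(world) {
  structure(list(
    predict = function(P) toy_predict(P, world),
    gradient = function(loss, P, context) toy_gradient(loss, P, world, context),
    world = world
  ), class = "predictor")
}

has_gradient <- function(predictor) is.function(predictor$gradient)
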