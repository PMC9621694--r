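#' Binning scheme for pairwise 6D features
#'
#' Bin edges for the four inter-residue channels: C-beta distance, the
#' omega and theta dihedrals and the phi planar angle. Defaults follow the
#' published trRosetta conventions: 36 equal distance bins over 2-20
#' Angstrom plus one no-contact state (37 states); omega and theta 24 bins
#' of 15 degrees plus no-contact (25); phi 12 bins of 15 degrees plus
#' no-contact (13). Pairs whose C-beta distance falls beyond the last
#' distance bin edge take the no-contact state in all four channels, as do
#' diagonal entries. The no-contact state is always the last state of a
#' channel.
#'
#' @param dist_min,dist_max Distance bin range in Angstrom.
#' @param n_dist Number of distance bins (excluding no-contact).
#' @param angle_step Angular bin width in degrees.
#' @return A `geometry_bins` list, one element per channel, each with
#'   `breaks` (bin edges) and `n` (number of states including no-contact).
#' @export
geometry_bins <- function(dist_min = 2, dist_max = 20, n_dist = 36,
                          angle_step = 15) {
  stopifnot(dist_max > dist_min, n_dist >= 1,
            360 %% angle_step == 0, 180 %% angle_step == 0)
  out <- list(
    dist  = list(breaks = seq(dist_min, dist_max, length.out = n_dist + 1),
                 n = n_dist + 1L),
    omega = list(breaks = seq(-180, 180, by = angle_step),
                 n = as.integer(360 / angle_step) + 1L),
    theta = list(breaks = seq(-180, 180, by = angle_step),
                 n = as.integer(360 / angle_step) + 1L),
    phi   = list(breaks = seq(0, 180, by = angle_step),
                 n = as.integer(180 / angle_step) + 1L)
  )
  structure(out, class = "geometry_bins")
}

geometry_channels <- c("dist", "omega", "theta", "phi")

# no-contact state index of a channel
no_contact_state <- function(bins, channel) bins[[channel]]$n

bin_value <- function(x, breaks) {
  # values exactly on an inner edge go to the upper bin; clamp end points
  i <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = TRUE)
  pmin(pmax(i, 1L), length(breaks) - 1L)
}

#' Assign 6D feature bins for every residue pair
#'
#' Computes, for each ordered residue pair (i, j), the binned C-beta
#' distance, omega dihedral (CAi-CBi-CBj-CAj), theta dihedral
#' (Ni-CAi-CBi-CBj) and phi planar angle (CAi-CBi-CBj). C-beta positions
#' are always the idealized virtual positions from [virtual_cb].
#'
#' @param x A [backbone] structure with at least 2 residues.
#' @param bins A [geometry_bins] scheme.
#' @return Named list of `L x L` integer bin-index matrices (one per
#'   channel); the last state of each channel is the no-contact state,
#'   assigned to diagonal entries and pairs beyond the last distance edge.
#' @export
sixd_bins <- function(x, bins = geometry_bins()) {
  L <- nrow(x)
  if (L < 2) stop("at least 2 residues are required")
  CB <- virtual_cb(x$N, x$CA, x$C)
  CA <- x$CA; N <- x$N

  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  d <- sqrt(rowSums((CB[ii, , drop = FALSE] - CB[jj, , drop = FALSE])^2))

  omega <- row_dihedral(CA[ii, ], CB[ii, ], CB[jj, ], CA[jj, ])
  theta <- row_dihedral(N[ii, ], CA[ii, ], CB[ii, ], CB[jj, ])
  phi <- row_angle(CA[ii, ], CB[ii, ], CB[jj, ])

  contact <- ii != jj & d <= max(bins$dist$breaks)
  assign1 <- function(vals, channel) {
    b <- rep(no_contact_state(bins, channel), L * L)
    b[contact] <- bin_value(vals[contact], bins[[channel]]$breaks)
    matrix(as.integer(b), L, L)
  }
  list(dist = assign1(d, "dist"), omega = assign1(omega, "omega"),
       theta = assign1(theta, "theta"), phi = assign1(phi, "phi"))
}

#' One-hot pairwise geometry of a structure
#'
#' Wraps [sixd_bins] output as a `pairwise_geometry` object in which every
#' pair distribution puts mass 1 on the observed bin.
#'
#' @inheritParams sixd_bins
#' @return A one-hot `pairwise_geometry`.
#' @export
sixd_features <- function(x, bins = geometry_bins()) {
  onehot_geometry(sixd_bins(x, bins), bins)
}

# ---- pairwise geometry representations -----------------------------------
#
# dense:   channels = list of L x L x B probability arrays
# mixture: conf (L x L, lambda) + ref_bins; each pair distribution is
#          lambda * onehot(ref bin) + (1 - lambda) * uniform(B).
# A one-hot geometry is a mixture with conf == 1. The mixture form is what
# the toy predictor emits; closed-form channel statistics on it keep the
# optimizers cheap, and as_dense_geometry() materializes it for generic code.

new_pairwise_geometry <- function(x, subclass) {
  structure(x, class = c(subclass, "pairwise_geometry"))
}

dense_geometry <- function(channels, bins) {
  L <- dim(channels[[1]])[1]
  new_pairwise_geometry(list(channels = channels, bins = bins, L = L),
                        "dense_geometry")
}

mixture_geometry <- function(conf, ref_bins, bins) {
  stopifnot(is.matrix(conf), all(conf >= -1e-9), all(conf <= 1 + 1e-9))
  new_pairwise_geometry(list(conf = pmin(pmax(conf, 0), 1),
                             ref_bins = ref_bins, bins = bins,
                             L = nrow(conf)),
                        "mixture_geometry")
}

onehot_geometry <- function(ref_bins, bins) {
  L <- nrow(ref_bins[[1]])
  mixture_geometry(matrix(1, L, L), ref_bins, bins)
}

#' @export
print.pairwise_geometry <- function(x, ...) {
  cat("<pairwise_geometry[", class(x)[1], "]> L = ", x$L, ", states: ",
      paste(vapply(geometry_channels, function(ch) x$bins[[ch]]$n, 1L),
            collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Materialize a pairwise geometry as dense probability arrays
#'
#' @param g A `pairwise_geometry`.
#' @return A dense `pairwise_geometry` whose channels are `L x L x B`
#'   arrays of normalized probability vectors.
#' @export
as_dense_geometry <- function(g) {
  if (inherits(g, "dense_geometry")) return(g)
  L <- g$L
  channels <- lapply(geometry_channels, function(ch) {
    B <- g$bins[[ch]]$n
    arr <- array(rep((1 - g$conf) / B, B), dim = c(L, L, B))
    idx <- cbind(rep(seq_len(L), L), rep(seq_len(L), each = L),
                 as.vector(g$ref_bins[[ch]]))
    arr[idx] <- arr[idx] + as.vector(g$conf)
    arr
  })
  names(channels) <- geometry_channels
  dense_geometry(channels, g$bins)
}

# ---- channel statistics (dispatch on representation) ---------------------

geom_nbins <- function(g, channel) g$bins[[channel]]$n

# probability mass at given bins for ordered pairs (i, j); all vectorized
geom_prob_at <- function(g, channel, i, j, bin) {
  B <- geom_nbins(g, channel)
  if (inherits(g, "mixture_geometry")) {
    lam <- g$conf[cbind(i, j)]
    hit <- g$ref_bins[[channel]][cbind(i, j)] == bin
    return(lam * as.numeric(hit) + (1 - lam) / B)
  }
  g$channels[[channel]][cbind(i, j, bin)]
}

# L x L Shannon entropy (nats) of each pair distribution in a channel
geom_entropy <- function(g, channel) {
  B <- geom_nbins(g, channel)
  if (inherits(g, "mixture_geometry")) {
    return(mixture_entropy(g$conf, B))
  }
  arr <- g$channels[[channel]]
  p <- pmax(arr, 0)
  -apply(p * log(pmax(p, 1e-300)), c(1, 2), sum)
}

# closed-form entropy of lambda*onehot + (1-lambda)*uniform(B)
mixture_entropy <- function(lam, B) {
  p1 <- lam + (1 - lam) / B
  p0 <- (1 - lam) / B
  -(p1 * log(pmax(p1, 1e-300)) + (B - 1) * p0 * log(pmax(p0, 1e-300)))
}

# d/d lambda of mixture_entropy
mixture_entropy_grad <- function(lam, B) {
  lam <- pmin(lam, 1 - 1e-12)
  p1 <- lam + (1 - lam) / B
  p0 <- (1 - lam) / B
  (1 - 1 / B) * (log(p0) - log(p1))
}

# L x L mass of the distance channel strictly within `cutoff` Angstrom:
# the summed probability of distance bins whose upper edge is <= cutoff
geom_contact_mass <- function(g, cutoff) {
  breaks <- g$bins$dist$breaks
  k <- sum(breaks[-1] <= cutoff)           # number of in-contact bins
  B <- g$bins$dist$n
  if (inherits(g, "mixture_geometry")) {
    hit <- g$ref_bins$dist <= k            # no-contact state is B > k
    return(g$conf * hit + (1 - g$conf) * k / B)
  }
  if (k == 0) return(matrix(0, g$L, g$L))
  apply(g$channels$dist[, , seq_len(k), drop = FALSE], c(1, 2), sum)
}
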