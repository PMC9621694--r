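#' Loss configuration
#'
#' A composite design loss is an ordered list of weighted terms, each a
#' pure function of a [prediction_result] plus configuration. Every term is
#' minimized (lower is better), so optimizer code is uniform. Available
#' terms:
#'
#' * `motif_ce` — motif distogram cross-entropy: mean over ordered
#'   motif-motif pairs and the four channels of `-log(predicted mass on the
#'   native bin + eps)`. Params: `eps` (default 1e-8).
#' * `motif_rmsd` — Kabsch-superposed backbone RMSD of the predicted motif
#'   region against the native motif, in Angstrom.
#' * `certainty` — mean Shannon entropy (nats) of the selected pair
#'   distributions (`mode = "entropy"`), or negative mean KL divergence
#'   from a background (`mode = "kl_background"`; uniform background by
#'   default). With an inter-chain pair mask this is the inter-chain
#'   entropy loss used for binder design. Params: `mode`, `pairs`
#'   (`"all"` or `"interchain"`).
#' * `repulsion` — mean contact probability (distance-channel mass within
#'   `cutoff`, default 8 Angstrom C-beta) over cross-chain pairs not in the
#'   allowed set; penalizes interface contacts beyond the scaffolded ones.
#' * `rog` — compactness: `max(0, Rg - rg_max)^2` on the CA radius of
#'   gyration. Params: `rg_max` (Angstrom, default 15).
#' * `pae` — mean predicted aligned error (Angstrom) over the selected
#'   ordered pairs (off-diagonal by default; `pairs = "interchain"`
#'   restricts to cross-chain pairs).
#'
#' @param ... [loss_term] objects (or bare term names, taken with weight 1).
#' @return A `loss_config`.
#' @examples
#' loss_config(loss_term("certainty", weight = 1),
#'             loss_term("motif_ce", weight = 2))
#' @export
loss_config <- function(...) {
  terms <- lapply(list(...), function(t) {
    if (is.character(t)) t <- loss_term(t)
    stopifnot(inherits(t, "loss_term"))
    t
  })
  if (length(terms) == 0) stop("at least one loss term is required")
  structure(terms, class = "loss_config")
}

#' @rdname loss_config
#' @param name Term name (see [loss_config]).
#' @param weight Finite real weight.
#' @export
loss_term <- function(name, weight = 1, ...) {
  if (!name %in% names(loss_registry)) {
    stop("unknown loss term '", name, "'; available: ",
         paste(names(loss_registry), collapse = ", "))
  }
  stopifnot(is.numeric(weight), is.finite(weight))
  structure(list(name = name, weight = weight, params = list(...)),
            class = "loss_term")
}

#' @export
print.loss_config <- function(x, ...) {
  cat("<loss_config>\n")
  for (t in x) {
    cat("  ", format(t$name, width = 10), " weight = ", t$weight,
        if (length(t$params))
          paste0("  (", paste(names(t$params), unlist(t$params), sep = "=",
                              collapse = ", "), ")"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a loss configuration as YAML
#'
#' The on-disk form is a list of `{name, weight, params}` entries.
#'
#' @param path YAML file path.
#' @return A [loss_config] (for reading); `path` invisibly (for writing).
#' @export
read_loss_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(loss_config, lapply(raw, function(e) {
    do.call(loss_term, c(list(name = e$name, weight = e$weight),
                         e$params %||% list()))
  }))
}

#' @rdname read_loss_config
#' @param config A [loss_config].
#' @export
write_loss_config <- function(config, path) {
  yaml::write_yaml(lapply(config, function(t) {
    list(name = t$name, weight = t$weight, params = t$params)
  }), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- context -------------------------------------------------------------

#' Assemble the evaluation context for a composite loss
#'
#' Bundles the quantities loss terms need beyond the prediction itself.
#' The native motif's 6D reference bins are computed here once.
#'
#' @param placement A `motif_placement` (see [sample_placement]).
#' @param native_motif Native motif [backbone] (from [extract_motif]).
#' @param allowed_pairs Optional 2-column matrix of ordered cross-chain
#'   (i, j) design-index pairs whose contact is permitted (repulsion term).
#' @param pair_mask Optional logical `L x L` mask of ordered pairs for the
#'   certainty / pae terms (default: all off-diagonal pairs).
#' @param bins [geometry_bins] for the motif reference features.
#' @return A `loss_context` list.
#' @export
loss_context <- function(placement = NULL, native_motif = NULL,
                         allowed_pairs = NULL, pair_mask = NULL,
                         bins = geometry_bins()) {
  motif_bins <- NULL
  if (!is.null(native_motif) && nrow(native_motif) >= 2) {
    motif_bins <- sixd_bins(native_motif, bins)
  }
  structure(list(placement = placement, native_motif = native_motif,
                 motif_bins = motif_bins, allowed_pairs = allowed_pairs,
                 pair_mask = pair_mask, bins = bins),
            class = "loss_context")
}

need_context <- function(context, what, term) {
  for (w in what) {
    if (is.null(context[[w]])) {
      stop("loss term '", term, "' requires context field '", w, "'")
    }
  }
}

# ordered-pair index matrix (i, j) for the selected mask
selected_pairs <- function(L, pair_mask = NULL, off_diagonal = TRUE) {
  if (is.null(pair_mask)) {
    pair_mask <- matrix(TRUE, L, L)
  }
  if (off_diagonal) diag(pair_mask) <- FALSE
  idx <- which(pair_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("pair mask selects no pairs")
  idx
}

interchain_mask <- function(L, boundary) {
  stopifnot(!is.null(boundary), boundary > 1, boundary <= L)
  one <- seq_len(boundary - 1)
  two <- boundary:L
  m <- matrix(FALSE, L, L)
  m[one, two] <- TRUE
  m[two, one] <- TRUE
  m
}

resolve_pair_mask <- function(pred, context, params) {
  L <- nrow(pred$coords)
  pairs <- params$pairs %||% "all"
  if (identical(pairs, "interchain")) {
    if (is.null(pred$chain_boundary)) stop("prediction has a single chain")
    return(interchain_mask(L, pred$chain_boundary))
  }
  context$pair_mask
}

# motif ordered-pair bookkeeping shared by value and gradient paths
motif_pair_table <- function(pred, context, params) {
  need_context(context, c("placement", "motif_bins"), "motif_ce")
  p <- context$placement$index_map$position
  M <- length(p)
  if (M < 2) stop("motif must contain at least 2 residues")
  ab <- selected_pairs(M)
  list(i = p[ab[, 1]], j = p[ab[, 2]], a = ab[, 1], b = ab[, 2], M = M)
}

# ---- term implementations ------------------------------------------------

term_motif_ce <- function(pred, context, params) {
  eps <- params$eps %||% 1e-8
  mp <- motif_pair_table(pred, context, params)
  total <- 0
  for (ch in geometry_channels) {
    truth <- context$motif_bins[[ch]][cbind(mp$a, mp$b)]
    q <- geom_prob_at(pred$geometry, ch, mp$i, mp$j, truth)
    total <- total + sum(-log(q + eps))
  }
  total / (length(mp$i) * length(geometry_channels))
}

grad_motif_ce <- function(pred, context, params) {
  eps <- params$eps %||% 1e-8
  mp <- motif_pair_table(pred, context, params)
  L <- nrow(pred$coords)
  G <- matrix(0, L, L)
  conf <- pred$geometry$conf[cbind(mp$i, mp$j)]
  denom <- length(mp$i) * length(geometry_channels)
  for (ch in geometry_channels) {
    B <- geom_nbins(pred$geometry, ch)
    truth <- context$motif_bins[[ch]][cbind(mp$a, mp$b)]
    delta <- as.numeric(pred$geometry$ref_bins[[ch]][cbind(mp$i, mp$j)] == truth)
    q <- conf * delta + (1 - conf) / B
    g <- -(delta - 1 / B) / (q + eps) / denom
    G[cbind(mp$i, mp$j)] <- G[cbind(mp$i, mp$j)] + g
  }
  G
}

term_motif_rmsd <- function(pred, context, params) {
  need_context(context, c("placement", "native_motif"), "motif_rmsd")
  motif_rmsd_metric(pred$coords, context$native_motif, context$placement,
                    atoms = params$atoms %||% c("N", "CA", "C"))
}

term_certainty <- function(pred, context, params) {
  mode <- params$mode %||% "entropy"
  idx <- selected_pairs(nrow(pred$coords),
                        resolve_pair_mask(pred, context, params))
  total <- 0
  for (ch in geometry_channels) {
    H <- geom_entropy(pred$geometry, ch)
    h <- mean(H[idx])
    if (mode == "entropy") {
      total <- total + h
    } else if (mode == "kl_background") {
      # KL to the uniform background is log(B) - H; loss is its negative
      total <- total - (log(geom_nbins(pred$geometry, ch)) - h)
    } else {
      stop("unknown certainty mode '", mode, "'")
    }
  }
  total / length(geometry_channels)
}

grad_certainty <- function(pred, context, params) {
  # entropy and kl_background differ by a constant: identical gradient
  idx <- selected_pairs(nrow(pred$coords),
                        resolve_pair_mask(pred, context, params))
  L <- nrow(pred$coords)
  G <- matrix(0, L, L)
  conf <- pred$geometry$conf[idx]
  g <- numeric(nrow(idx))
  for (ch in geometry_channels) {
    B <- geom_nbins(pred$geometry, ch)
    g <- g + mixture_entropy_grad(conf, B)
  }
  G[idx] <- g / (nrow(idx) * length(geometry_channels))
  G
}

repulsion_pairs <- function(pred, context) {
  if (is.null(pred$chain_boundary)) {
    stop("repulsion loss requires a two-chain prediction")
  }
  L <- nrow(pred$coords)
  idx <- which(interchain_mask(L, pred$chain_boundary), arr.ind = TRUE)
  if (!is.null(context$allowed_pairs)) {
    allowed <- paste(context$allowed_pairs[, 1], context$allowed_pairs[, 2])
    idx <- idx[!paste(idx[, 1], idx[, 2]) %in% allowed, , drop = FALSE]
  }
  if (nrow(idx) == 0) stop("no disallowed cross-chain pairs")
  idx
}

term_repulsion <- function(pred, context, params) {
  cutoff <- params$cutoff %||% 8
  idx <- repulsion_pairs(pred, context)
  mean(geom_contact_mass(pred$geometry, cutoff)[idx])
}

grad_repulsion <- function(pred, context, params) {
  cutoff <- params$cutoff %||% 8
  idx <- repulsion_pairs(pred, context)
  g <- pred$geometry
  k <- sum(g$bins$dist$breaks[-1] <= cutoff)
  B <- g$bins$dist$n
  L <- nrow(pred$coords)
  G <- matrix(0, L, L)
  delta <- as.numeric(g$ref_bins$dist[idx] <= k)
  G[idx] <- (delta - k / B) / nrow(idx)
  G
}

term_rog <- function(pred, context, params) {
  rg_max <- params$rg_max %||% 15
  max(0, radius_of_gyration(pred$coords) - rg_max)^2
}

term_pae <- function(pred, context, params) {
  idx <- selected_pairs(nrow(pred$coords),
                        resolve_pair_mask(pred, context, params))
  mean(pred$pae[idx])
}

grad_pae <- function(pred, context, params) {
  idx <- selected_pairs(nrow(pred$coords),
                        resolve_pair_mask(pred, context, params))
  L <- nrow(pred$coords)
  G <- matrix(0, L, L)
  # toy pae_ij = max_pae * (1 - c_ij); recover the cap from any entry
  max_pae <- unique_max_pae(pred)
  G[idx] <- -max_pae / nrow(idx)
  G
}

unique_max_pae <- function(pred) {
  conf <- pred$geometry$conf
  off <- abs(1 - conf) > 1e-12
  if (!any(off)) return(0)
  (pred$pae[off] / (1 - conf[off]))[1]
}

# gradient = NULL marks a term that is constant in the sequence under the
# toy predictor (its value depends only on the planted coordinates)
loss_registry <- list(
  motif_ce   = list(fn = term_motif_ce,   grad = grad_motif_ce),
  motif_rmsd = list(fn = term_motif_rmsd, grad = NULL),
  certainty  = list(fn = term_certainty,  grad = grad_certainty),
  repulsion  = list(fn = term_repulsion,  grad = grad_repulsion),
  rog        = list(fn = term_rog,        grad = NULL),
  pae        = list(fn = term_pae,        grad = grad_pae)
)

#' Evaluate a composite loss
#'
#' @param pred A [prediction_result].
#' @param config A [loss_config].
#' @param context A [loss_context] with whatever the enabled terms need.
#' @return List with `total` (weighted sum) and `breakdown`, a tibble of
#'   per-term unweighted values, weights and weighted contributions.
#' @export
composite_loss <- function(pred, config, context = loss_context()) {
  stopifnot(inherits(config, "loss_config"))
  vals <- vapply(config, function(t) {
    loss_registry[[t$name]]$fn(pred, context, t$params)
  }, numeric(1))
  w <- vapply(config, `[[`, numeric(1), "weight")
  breakdown <- tibble::tibble(
    term = vapply(config, `[[`, character(1), "name"),
    weight = w, value = vals, weighted = w * vals
  )
  list(total = sum(breakdown$weighted), breakdown = breakdown)
}

#' Analytic sequence-space gradient on the toy landscape
#'
#' Exact derivative of a composite loss with respect to every entry of the
#' sequence distribution `P`, for predictions produced by [toy_predict].
#' All toy outputs are closed-form in the local agreement `a` (and pair
#' confidence `c = a a'`), so the chain rule runs loss -> c -> a -> m -> P.
#' Terms that depend only on the planted coordinates (`motif_rmsd`, `rog`)
#' are constant in `P` and contribute zero.
#'
#' @param config A [loss_config].
#' @param P `L x 20` sequence distribution.
#' @param world A [planted_landscape].
#' @param context A [loss_context].
#' @return `L x 20` gradient matrix (nonzero only in the planted-letter
#'   column of each row, since the toy forward pass reads only
#'   `P_i(s*_i)`).
#' @export
toy_gradient <- function(config, P, world, context = loss_context()) {
  stopifnot(inherits(config, "loss_config"))
  pred <- toy_predict(P, world)
  L <- nrow(P)

  G <- matrix(0, L, L)        # dL/dc over ordered pairs
  for (t in config) {
    entry <- loss_registry[[t$name]]
    if (is.null(entry$grad)) next
    G <- G + t$weight * entry$grad(pred, context, t$params)
  }

  # c_kj = a_k a_j  =>  dL/da_k = sum_j (G[k,j] + G[j,k]) a_j; the j = k
  # entry of the sum is 2 G[k,k] a_k, the correct derivative of c_kk = a_k^2
  m <- P[cbind(seq_len(L), match(world$sequence, aa_alphabet))]
  a <- window_agreement(m, world)
  dL_da <- as.numeric((G + t(G)) %*% a)

  # a_k = mean of m over window W_k  =>  dL/dm_i = sum_{k: i in W_k} dL/da_k / |W_k|
  dL_dm <- numeric(L)
  w <- world$window
  for (b in chain_ranges(world)) {
    for (k in b[1]:b[2]) {
      lo <- max(b[1], k - w); hi <- min(b[2], k + w)
      dL_dm[lo:hi] <- dL_dm[lo:hi] + dL_da[k] / (hi - lo + 1)
    }
  }

  out <- matrix(0, L, 20, dimnames = list(NULL, aa_alphabet))
  out[cbind(seq_len(L), match(world$sequence, aa_alphabet))] <- dL_dm
  out
}
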