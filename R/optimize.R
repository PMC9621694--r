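#' Geometric annealing schedule
#'
#' Temperatures interpolate geometrically from `T0` to `Tf`:
#' `T_k = T0 * (Tf/T0)^(k/K)`. When `T0` is `NULL`, [mcmc_design]
#' calibrates it at run time as 0.1 times the mean absolute loss change of
#' a short probe of random single mutations from the initial sequence --
#' the scale on which the Metropolis criterion actually operates -- and
#' sets `Tf = T0/100`.
#'
#' @param steps Number of Monte Carlo steps `K >= 0`.
#' @param T0,Tf Initial and final temperatures, `T0 >= Tf > 0`, or `NULL`
#'   for run-time calibration.
#' @return An `anneal_schedule`.
#' @export
anneal_schedule <- function(steps, T0 = NULL, Tf = NULL) {
  stopifnot(steps >= 0)
  if (!is.null(T0)) {
    if (is.null(Tf)) Tf <- T0 / 100
    stopifnot(T0 > 0, Tf > 0, T0 >= Tf)
  }
  structure(list(steps = as.integer(steps), T0 = T0, Tf = Tf),
            class = "anneal_schedule")
}

schedule_temperature <- function(schedule, k) {
  with(schedule, T0 * (Tf / T0)^(k / max(steps, 1)))
}

#' Metropolis acceptance criterion
#'
#' Accepts every improving move; a worsening move is accepted with
#' probability `exp(-delta_loss / T)`.
#'
#' @param delta_loss Proposed loss minus current loss.
#' @param T Temperature, `> 0`.
#' @param u Uniform(0,1) draw; by default taken from the calling RNG scope.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_loss, T, u = stats::runif(1)) {
  if (T <= 0) stop("temperature must be positive")
  delta_loss < 0 || u < exp(-delta_loss / T)
}

#' Initial design sequence for a placement
#'
#' Motif positions carry the native motif letters; scaffold positions are
#' sampled from the mutation alphabet.
#'
#' @param placement A `motif_placement`.
#' @param native_motif Native motif [backbone] (residues in token order).
#' @param seed Integer seed for the scaffold letters.
#' @param alphabet Scaffold alphabet (default [mutation_alphabet]).
#' @return Character vector of length `placement$total_length`.
#' @export
init_design_sequence <- function(placement, native_motif, seed = 1,
                                 alphabet = mutation_alphabet()) {
  seq <- random_sequence(placement$total_length, seed, alphabet)
  seq[placement$index_map$position] <- native_motif$aa
  seq
}

new_trajectory <- function(steps, breakdown, best, method, provenance) {
  structure(list(steps = steps, breakdown = breakdown, best = best,
                 method = method, provenance = provenance),
            class = "design_trajectory")
}

#' @export
print.design_trajectory <- function(x, ...) {
  cat("<design_trajectory[", x$method, "]> ", nrow(x$steps) - 1, " steps, ",
      "best loss ", signif(x$best$loss, 5), "\n", sep = "")
  invisible(x)
}

#' Sequence design by Metropolis simulated annealing
#'
#' Monte Carlo sampling in sequence space: at each step a single non-motif
#' position is mutated (uniformly over the allowed alphabet, excluding the
#' current letter), the predictor is re-run, and the move is accepted by
#' the Metropolis criterion under a geometric cooling schedule. Motif
#' positions are never mutable. The current state's prediction is cached,
#' so each step costs one predictor call.
#'
#' @param predictor A predictor object (e.g. [toy_predictor]).
#' @param config A [loss_config].
#' @param context A [loss_context] (must carry the placement's needs).
#' @param placement A `motif_placement`.
#' @param init Initial sequence (character vector of length L); motif
#'   positions are forced to the native motif letters when
#'   `context$native_motif` is present.
#' @param schedule An [anneal_schedule].
#' @param seed Integer seed; trajectories are bit-identical under identical
#'   seeds and configurations.
#' @param alphabet Proposal alphabet (default [mutation_alphabet]).
#' @return A `design_trajectory`: per-step records (tibble `steps`),
#'   per-step loss breakdown (`breakdown`), and the best design (`best`).
#' @export
mcmc_design <- function(predictor, config, context, placement, init,
                        schedule = anneal_schedule(1000), seed = 1,
                        alphabet = mutation_alphabet()) {
  L <- placement$total_length
  stopifnot(length(init) == L)
  seq <- split_sequence(init)
  if (!is.null(context$native_motif)) {
    seq[placement$index_map$position] <- context$native_motif$aa
  }
  mutable <- which(!placement$motif_mask)
  if (length(mutable) == 0) stop("placement has no mutable positions")

  evaluate <- function(s) composite_loss(predictor$predict(s), config, context)

  with_seed(seed, {
    cur <- evaluate(seq)
    T0 <- schedule$T0
    if (is.null(T0)) {
      probe <- vapply(seq_len(20), function(i) {
        s2 <- propose_mutation(seq, mutable, alphabet)
        abs(evaluate(s2)$total - cur$total)
      }, numeric(1))
      T0 <- max(0.1 * mean(probe), 1e-6)
      schedule <- anneal_schedule(schedule$steps, T0 = T0)
    }

    K <- schedule$steps
    rows <- vector("list", K + 1)
    bd <- vector("list", K + 1)
    best <- list(sequence = seq, loss = cur$total, step = 0L)
    rows[[1]] <- tibble::tibble(step = 0L,
                                sequence = collapse_sequence(seq),
                                loss = cur$total, temperature = T0,
                                accepted = NA, best_loss = cur$total)
    bd[[1]] <- cur$breakdown$value
    if (K > 0) {
      for (k in seq_len(K)) {
        Tk <- schedule_temperature(schedule, k)
        prop_seq <- propose_mutation(seq, mutable, alphabet)
        prop <- evaluate(prop_seq)
        acc <- metropolis_accept(prop$total - cur$total, Tk)
        if (acc) {
          seq <- prop_seq; cur <- prop
          if (cur$total < best$loss) {
            best <- list(sequence = seq, loss = cur$total, step = k)
          }
        }
        rows[[k + 1]] <- tibble::tibble(step = k,
                                        sequence = collapse_sequence(seq),
                                        loss = cur$total, temperature = Tk,
                                        accepted = acc,
                                        best_loss = best$loss)
        bd[[k + 1]] <- cur$breakdown$value
      }
    }
  })

  breakdown <- as_breakdown_tibble(bd, cur$breakdown$term)
  new_trajectory(dplyr::bind_rows(rows), breakdown, best, "mcmc",
                 list(seed = seed, schedule = unclass(schedule),
                      alphabet = alphabet))
}

propose_mutation <- function(seq, mutable, alphabet) {
  pos <- if (length(mutable) == 1) mutable else sample(mutable, 1)
  options <- setdiff(alphabet, seq[pos])
  seq[pos] <- if (length(options) == 1) options else sample(options, 1)
  seq
}

as_breakdown_tibble <- function(bd, terms) {
  m <- do.call(rbind, bd)
  colnames(m) <- terms
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out$step <- seq_len(nrow(out)) - 1L
  out[, c("step", terms)]
}

#' Sequence design by gradient descent on logits
#'
#' The optimization variable is an `L x 20` logit matrix; the sequence
#' distribution is its row-wise softmax (temperature 1). Motif rows are
#' clamped to one-hot native letters and receive no updates. Requires a
#' predictor exposing the analytic-gradient capability. With
#' `straight_through = TRUE` the loss and gradient are evaluated at the
#' one-hot argmax of the current distribution instead of the soft
#' distribution.
#'
#' @inheritParams mcmc_design
#' @param init Initial `L x 20` logit matrix, or `NULL` for a seeded
#'   random draw (standard normal logits, scale 0.5).
#' @param steps Number of descent steps.
#' @param learning_rate Scalar step size, or a vector of length `steps`.
#' @param straight_through Evaluate at the hard argmax sequence (off by
#'   default).
#' @return A `design_trajectory`; the final design is the per-position
#'   argmax.
#' @export
gradient_design <- function(predictor, config, context, placement,
                            init = NULL, steps = 100, learning_rate = 1,
                            seed = 1, straight_through = FALSE) {
  if (!has_gradient(predictor)) {
    stop("predictor does not expose a gradient capability")
  }
  L <- placement$total_length
  logits <- init %||% with_seed(seed, {
    matrix(stats::rnorm(L * 20, sd = 0.5), L, 20,
           dimnames = list(NULL, aa_alphabet))
  })
  stopifnot(all(dim(logits) == c(L, 20)))
  lr <- rep_len(learning_rate, max(steps, 1))
  motif_rows <- placement$index_map$position
  motif_onehot <- NULL
  if (!is.null(context$native_motif)) {
    motif_onehot <- one_hot_sequence(context$native_motif$aa)
  }

  soft <- function(logits) {
    P <- exp(logits - apply(logits, 1, max))
    P <- P / rowSums(P)
    if (!is.null(motif_onehot)) P[motif_rows, ] <- motif_onehot
    P
  }
  eval_at <- function(P) {
    Q <- if (straight_through) one_hot_sequence(argmax_sequence(P)) else P
    list(loss = composite_loss(predictor$predict(Q), config, context),
         grad = predictor$gradient(config, Q, context))
  }

  rows <- vector("list", steps + 1)
  bd <- vector("list", steps + 1)
  P <- soft(logits)
  cur <- eval_at(P)
  best <- list(sequence = argmax_sequence(P), loss = cur$loss$total,
               step = 0L, logits = logits)
  rows[[1]] <- tibble::tibble(step = 0L,
                              sequence = collapse_sequence(best$sequence),
                              loss = cur$loss$total, accepted = NA,
                              best_loss = cur$loss$total)
  bd[[1]] <- cur$loss$breakdown$value
  if (steps > 0) {
    for (k in seq_len(steps)) {
      # chain softmax: dL/dz_it = P_it * (g_it - sum_u g_iu P_iu)
      g <- cur$grad
      rowdot <- rowSums(g * P)
      step_grad <- P * (g - rowdot)
      step_grad[motif_rows, ] <- 0
      logits <- logits - lr[k] * step_grad
      P <- soft(logits)
      cur <- eval_at(P)
      if (cur$loss$total < best$loss) {
        best <- list(sequence = argmax_sequence(P), loss = cur$loss$total,
                     step = k, logits = logits)
      }
      rows[[k + 1]] <- tibble::tibble(
        step = k, sequence = collapse_sequence(argmax_sequence(P)),
        loss = cur$loss$total, accepted = NA, best_loss = best$loss)
      bd[[k + 1]] <- cur$loss$breakdown$value
    }
  }

  breakdown <- as_breakdown_tibble(bd, cur$loss$breakdown$term)
  new_trajectory(dplyr::bind_rows(rows), breakdown, best, "gradient",
                 list(seed = seed, steps = steps,
                      learning_rate = learning_rate,
                      straight_through = straight_through))
}

#' Staged multi-protocol design
#'
#' Runs a list of optimization stages, each with its own optimizer, loss
#' configuration and step budget; stage `k + 1` is initialized from stage
#' `k`'s best design (a hard MCMC sequence entering a gradient stage is
#' lifted to one-hot logits; a gradient stage entering MCMC hands over its
#' argmax sequence). Stage-specific loss functions are the mechanism for
#' protocols such as a smoothed first stage followed by a sharper second
#' stage.
#'
#' @param stages List of stages; each a list with `optimizer` (`"mcmc"` or
#'   `"gradient"`), `config` (a [loss_config]), `steps`, and optional
#'   optimizer arguments (`learning_rate`, `T0`, `Tf`, `alphabet`).
#' @param predictor,context,placement As in [mcmc_design].
#' @param init Initial sequence for stage 1 (default: random scaffold via
#'   [init_design_sequence], which requires `context$native_motif`).
#' @param seed Integer seed; stage `k` derives its own sub-seed.
#' @return List of per-stage `design_trajectory` objects with class
#'   `staged_design`; `$best` holds the final stage's best design and
#'   `$provenance` every stage configuration.
#' @export
staged_protocol <- function(stages, predictor, context, placement,
                            init = NULL, seed = 1) {
  if (length(stages) == 0) stop("at least one stage is required")
  if (is.null(init)) {
    init <- init_design_sequence(placement, context$native_motif, seed)
  }
  carry <- split_sequence(init)
  trajectories <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    sub_seed <- seed + 1000L * (s - 1L)
    if (identical(st$optimizer, "mcmc")) {
      traj <- mcmc_design(
        predictor, st$config, context, placement, init = carry,
        schedule = anneal_schedule(st$steps, T0 = st$T0, Tf = st$Tf),
        seed = sub_seed, alphabet = st$alphabet %||% mutation_alphabet())
      carry <- traj$best$sequence
    } else if (identical(st$optimizer, "gradient")) {
      logits <- lift_to_logits(carry)
      traj <- gradient_design(
        predictor, st$config, context, placement, init = logits,
        steps = st$steps, learning_rate = st$learning_rate %||% 1,
        seed = sub_seed)
      carry <- traj$best$sequence
    } else {
      stop("unknown optimizer '", st$optimizer, "'")
    }
    trajectories[[s]] <- traj
  }
  structure(list(
    stages = trajectories,
    best = trajectories[[length(trajectories)]]$best,
    provenance = list(seed = seed, n_stages = length(stages),
                      stage_configs = lapply(stages, function(st) {
                        list(optimizer = st$optimizer, steps = st$steps)
                      }))
  ), class = "staged_design")
}

# one-hot lift of a hard sequence into logit space (scale 8 keeps the
# softmax essentially one-hot while leaving gradients finite)
lift_to_logits <- function(seq, scale = 8) {
  scale * one_hot_sequence(seq)
}
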