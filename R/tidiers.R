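#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a design trajectory
#'
#' @param x A `design_trajectory`.
#' @param breakdown Join the per-step unweighted loss breakdown columns.
#' @param ... Unused.
#' @return Tibble with one row per step: `step`, `sequence`, `loss`,
#'   `accepted`, `best_loss` (and `temperature` for MCMC runs).
#' @export
tidy.design_trajectory <- function(x, breakdown = FALSE, ...) {
  out <- x$steps
  if (breakdown) out <- dplyr::left_join(out, x$breakdown, by = "step")
  out
}

#' One-row summary of a design trajectory
#'
#' @param x A `design_trajectory`.
#' @param ... Unused.
#' @return Tibble: method, steps, initial/final/best loss, best step and
#'   acceptance rate (NA for gradient runs).
#' @export
glance.design_trajectory <- function(x, ...) {
  s <- x$steps
  tibble::tibble(
    method = x$method,
    n_steps = max(s$step),
    initial_loss = s$loss[1],
    final_loss = s$loss[nrow(s)],
    best_loss = x$best$loss,
    best_step = x$best$step,
    accept_rate = if (all(is.na(s$accepted))) NA_real_
                  else mean(s$accepted, na.rm = TRUE)
  )
}

#' Tidy a staged design
#'
#' @param x A `staged_design`.
#' @param ... Passed to [tidy.design_trajectory].
#' @return Per-step tibble across stages with a `stage` column.
#' @export
tidy.staged_design <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$stages), function(s) {
    dplyr::mutate(tidy(x$stages[[s]], ...), stage = s, .before = 1)
  }))
}

#' @rdname tidy.staged_design
#' @export
glance.staged_design <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$stages), function(s) {
    dplyr::mutate(glance(x$stages[[s]]), stage = s, .before = 1)
  }))
}

#' Plot a design trajectory
#'
#' Loss (and best-so-far envelope) against optimization step.
#'
#' @param object A `design_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.design_trajectory <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_loss), colour = "black") +
    ggplot2::labs(x = "step", y = "composite loss",
                  title = paste0(object$method, " design trajectory")) +
    ggplot2::theme_minimal()
}

#' Plot a masked-region benchmark
#'
#' Per-record distributions of fixed-region RMSD and masked-region
#' sequence recovery, with per-record means overlaid.
#'
#' @param object An `inpaint_benchmark` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.inpaint_benchmark <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("fixed_rmsd", "seq_recovery"),
                           names_to = "metric")
  avg <- dplyr::summarise(dplyr::group_by(d, .data$record, .data$metric),
                          value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$record),
                                  y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = avg, colour = "red", size = 2.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "record", y = NULL,
                  title = "Masked-region recovery benchmark") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
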