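#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a design result
#'
#' One row per position of the target: the designed base, the target and
#' achieved structure characters, and whether they agree.
#'
#' @param x An `erd_design` object.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `target`, `mfe`,
#'   `match`.
#' @method tidy erd_design
#' @export
tidy.erd_design <- function(x, ...) {
  tibble::tibble(
    position = seq_len(nchar(x$seq)),
    base = strsplit(x$seq, "", fixed = TRUE)[[1]],
    target = strsplit(x$target, "", fixed = TRUE)[[1]],
    mfe = strsplit(x$mfe_structure, "", fixed = TRUE)[[1]],
    match = .data$target == .data$mfe
  )
}

#' One-row summary of a design result
#'
#' @param x An `erd_design` object.
#' @param ... Unused.
#' @return A one-row tibble: `success`, `distance`, `energy_on_target`,
#'   `iterations_used`, `sequence_constraints_met`, `energy_constraint_met`,
#'   `length`, `engine`.
#' @method glance erd_design
#' @export
glance.erd_design <- function(x, ...) {
  tibble::tibble(
    success = x$success,
    distance = x$distance,
    energy_on_target = x$energy_on_target,
    iterations_used = x$iterations_used,
    sequence_constraints_met = x$sequence_constraints_met,
    energy_constraint_met = x$energy_constraint_met,
    length = nchar(x$seq),
    engine = x$engine
  )
}

#' Plot a design result
#'
#' Per-position view of the designed sequence: target versus achieved
#' structure state, mismatched positions highlighted.
#'
#' @param object An `erd_design` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erd_design
#' @export
autoplot.erd_design <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, c("target", "mfe"),
                              names_to = "which", values_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$which,
                                     fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(td, !.data$match),
                        ggplot2::aes(x = .data$position, y = 1.5),
                        inherit.aes = FALSE, shape = 4, size = 2) +
    ggplot2::scale_fill_manual(values = c("(" = "#3B6FB6", ")" = "#A6C8F0",
                                          "." = "grey85")) +
    ggplot2::labs(x = "position", y = NULL, fill = "state",
                  title = sprintf("design: distance %d, energy %.2f",
                                  object$distance, object$energy_on_target)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a nucleotide/base-pair distribution table
#'
#' Bar chart of the fractions per region, optionally against a reference
#' distribution (e.g. the natural composition).
#'
#' @param dist Tibble from [nucleotide_distribution()].
#' @param reference Optional second distribution tibble for comparison.
#' @return A ggplot object.
#' @export
plot_distribution <- function(dist, reference = NULL) {
  dist$source <- "observed"
  if (!is.null(reference)) {
    reference$source <- "reference"
    dist <- dplyr::bind_rows(dist, reference)
  }
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$symbol, y = .data$fraction,
                                     fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "fraction") +
    ggplot2::theme_minimal()
}
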