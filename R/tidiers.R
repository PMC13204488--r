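#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ANOVA result
#'
#' @param x An `anova_result` from [oneway_anova()].
#' @param ... Unused.
#' @return A one-row tibble with the F statistic, p value, degrees of
#'   freedom, sums of squares and the degeneracy flag.
#' @export
tidy.anova_result <- function(x, ...) {
  tibble::tibble(f_value = x$f_value, p_value = x$p_value,
                 df_between = x$df_between, df_within = x$df_within,
                 ss_between = x$ss_between, ss_within = x$ss_within,
                 degenerate = x$degenerate)
}

#' @rdname tidy.anova_result
#' @export
glance.anova_result <- function(x, ...) tidy(x, ...)

#' Tidy a readout model
#'
#' @param x A `readout_model` from [train_readout()].
#' @param ... Unused.
#' @return A long tibble of readout weights (`reservoir_neuron`, `class`,
#'   `weight`).
#' @export
tidy.readout_model <- function(x, ...) {
  tibble::tibble(
    reservoir_neuron = rep(seq_len(nrow(x$weights)), ncol(x$weights)),
    class = rep(x$classes, each = nrow(x$weights)),
    weight = as.vector(x$weights)
  )
}

#' @rdname tidy.readout_model
#' @export
glance.readout_model <- function(x, ...) {
  tibble::tibble(
    n_reservoir = nrow(x$weights),
    n_classes = ncol(x$weights),
    cycles = x$params$cycles,
    initial_vr_distance = if (nrow(x$history)) x$history$mean_vr_distance[1]
                          else NA_real_,
    final_vr_distance = if (nrow(x$history)) {
      utils::tail(x$history$mean_vr_distance, 1)
    } else {
      NA_real_
    }
  )
}
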