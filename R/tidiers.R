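# broom-style accessors for simulation objects.

#' Tidy a simulation into a long population table
#'
#' @param x A `cd8_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `mcs`, `day`, `type`, `count`: one row per
#'   snapshot and cell type.
#' @export
tidy.cd8_sim <- function(x, ...) {
  tidyr::pivot_longer(x$population,
                      cols = c("naive", "pre_activated", "activated",
                               "effector", "memory", "apc"),
                      names_to = "type", values_to = "count")
}

#' One-row summary of a simulation
#'
#' @param x A `cd8_sim` object.
#' @param ... Passed to [summarize_run()].
#' @return A one-row tibble with peak size/day, the activated+effector
#'   fraction at the peak, memory counts, the contraction death fraction and
#'   the memory-generation efficiency ratio.
#' @export
glance.cd8_sim <- function(x, ...) {
  summarize_run(x, ...)
}
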