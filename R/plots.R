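# ggplot2 visualisations for simulation results.

#' Plot population dynamics of a run
#'
#' Counts by cell type over days post-infection, on top of the total CD8
#' population.
#'
#' @param object A `cd8_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cd8_sim <- function(object, ...) {
  long <- tidy.cd8_sim(object)
  long <- long[long$type != "apc", ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$count,
                                     colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = object$population,
                       mapping = ggplot2::aes(x = .data$day, y = .data$total_cd8),
                       colour = "black", linetype = "dashed",
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "day post-infection", y = "cells",
                  colour = "cell type",
                  title = sprintf("CD8 T-cell %s response", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a ranked Tbet profile
#'
#' Cells sorted by Tbet with Eomes and Caspases overlaid (scaled by a factor
#' for readability) and the unstable Tbet fixed point marked.
#'
#' @param profile Output of [tbet_profile()].
#' @param scale_factor Multiplier applied to Eomes and Caspases for display.
#' @return A ggplot.
#' @export
plot_tbet_profile <- function(profile, scale_factor = 5) {
  tbu <- attr(profile, "tb_unstable")
  df <- tibble::tibble(
    rank = rep(profile$rank, 3),
    value = c(profile$Tb, profile$E * scale_factor, profile$Cas * scale_factor),
    protein = rep(c("Tbet", sprintf("Eomes x%g", scale_factor),
                    sprintf("Caspases x%g", scale_factor)),
                  each = nrow(profile))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                        colour = .data$protein)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "cells ranked by Tbet", y = "concentration (mol/L)") +
    ggplot2::theme_minimal()
  if (!is.null(tbu) && !is.na(tbu))
    p <- p + ggplot2::geom_hline(yintercept = tbu, linetype = "dotted")
  p
}

#' Plot an unevenness sweep
#'
#' Mean peak size and memory pool (left axis, log scale not used) and the
#' memory-generation efficiency ratio against the degree of unevenness.
#'
#' @param object A `cd8_sweep` tibble from [sweep_unevenness()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cd8_sweep <- function(object, ...) {
  s <- summarize_sweep(object)
  long <- tidyr::pivot_longer(s[, c("m", "peak_mean", "memory_mean")],
                              cols = c("peak_mean", "memory_mean"),
                              names_to = "what", values_to = "cells")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$cells,
                                     colour = .data$what)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "degree of unevenness m (%)", y = "cells (mean)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the lattice
#'
#' Final (or supplied) lattice coloured by cell type.
#'
#' @param sim A `cd8_sim` object, or an integer sigma matrix.
#' @param cells When `sim` is a matrix: data frame with `id`, `type`.
#' @return A ggplot.
#' @export
plot_lattice <- function(sim, cells = NULL) {
  if (inherits(sim, "cd8_sim")) {
    sigma <- sim$final_sigma
    cells <- sim$final_cells
  } else sigma <- sim
  lk <- c("0" = "medium", setNames(cells$type, cells$id))
  df <- tibble::tibble(
    row = as.vector(row(sigma)), col = as.vector(col(sigma)),
    type = unname(lk[as.character(as.vector(sigma))])
  )
  df$type[is.na(df$type)] <- "medium"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(
      medium = "grey95", apc = "grey40", naive = "#7fc97f",
      pre_activated = "#beaed4", activated = "#fdc086", effector = "#d95f02",
      memory = "#386cb0"), drop = FALSE) +
    ggplot2::theme_void()
}
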