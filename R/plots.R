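#' Plot a run's species dynamics
#'
#' Census trajectories over time, one line per category, in the colour
#' idiom of this model family (REP in blues, NR in reds, controls in
#' greens).  Categories that stay at zero throughout are dropped.
#'
#' @param object an `rw_run`.
#' @param categories which categories to show (default: all with a nonzero
#'   observation).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot rw_run
#' @export
autoplot.rw_run <- function(object, categories = NULL, ...) {
  long <- tidy(object)
  if (is.null(categories)) {
    keep <- long %>% group_by(.data$category) %>%
      summarise(any = any(.data$count > 0), .groups = "drop") %>%
      filter(.data$any) %>% pull(.data$category)
    categories <- as.character(keep)
  }
  long <- long %>% filter(.data$category %in% categories)
  pal <- c(cir_rep = "#1f4e9c", cir_repcom = "#7fb2e5", lin_rep = "#16324f",
           lin_repcom = "#5c87a8", cir_ct = "#2e8b57", cir_ctcom = "#90d4a8",
           cir_repnr = "#000000", cir_nr = "#c0392b", lin_rep_rib = "#3a6ccc",
           lin_nr_rib = "#e67e22")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$count,
                                     colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = pal, drop = TRUE) +
    ggplot2::labs(x = "Monte Carlo step", y = "molecules", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot genome-length dynamics
#'
#' The abundance of REP-carrying circular genomes by chain length over time
#' -- the panel in which an 8-nt compact genome is overtaken by a 9-12-nt
#' genome carrying a noncoding insertion.
#'
#' @param run an `rw_run`.
#' @return a ggplot.
#' @export
plot_genome_lengths <- function(run) {
  gl <- run$genome_lengths
  if (!nrow(gl)) abort("no circular REP genomes were observed in this run")
  gl$length <- factor(paste0(gl$length, "nt"),
                      levels = paste0(sort(unique(gl$length)), "nt"))
  ggplot2::ggplot(gl, ggplot2::aes(x = .data$step, y = .data$count,
                                   colour = .data$length)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Monte Carlo step", y = "circular REP genomes",
                  colour = "genome length") +
    ggplot2::theme_minimal()
}

#' Plot a spatial snapshot
#'
#' One tile map of the grid for a chosen channel of a recorded snapshot
#' (precursors as the classic yellow background; molecule categories as
#' filled tiles).
#'
#' @param run an `rw_run` with recorded snapshots.
#' @param step the snapshot step (must be one of the recorded ones).
#' @param channel channel name, e.g. `"precursors"` or `"cir_rep"`.
#' @return a ggplot.
#' @export
plot_snapshot <- function(run, step, channel = "precursors") {
  steps <- vapply(run$snapshots, function(s) s$step, numeric(1))
  i <- match(step, steps)
  if (is.na(i)) {
    abort(paste0("no snapshot at step ", step, "; recorded: ",
                 paste(steps, collapse = ", ")))
  }
  m <- run$snapshots[[i]]$channels[[channel]]
  if (is.null(m)) abort(paste0("unknown snapshot channel '", channel, "'"))
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$count <- as.vector(m)
  fill_high <- if (channel == "precursors") "#e6b800" else "#1f4e9c"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = fill_high) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(channel, " at step ",
                                 format(step, big.mark = ",")),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
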