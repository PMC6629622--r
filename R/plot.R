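#' State colour mapping for sequence index plots
#'
#' Fixed state-to-colour mapping used in every sequence index plot.
#'
#' @return Named character vector of colours over
#'   `state_alphabet(include_missing = TRUE)`.
#' @export
state_colors <- function() {
  c(NORMAL = "#4daf4a", HYPOPNEA = "#377eb8", BRADYPNEA = "#ff7f00",
    APNEA = "#e41a1c", MISSING = "grey85")
}

#' Sequence index plot
#'
#' Draws each patient's respiratory state sequence as one horizontal bar of
#' colour-coded segments proportional to the time spent in each state, one
#' panel per group (typically the clusters of a typology). Within a panel,
#' patients are sorted by sequence length (longest on top).
#'
#' @param seqs named list of per-second state code vectors.
#' @param groups optional vector of group labels named by (or aligned with)
#'   patient id; one panel is drawn per group. Default: a single panel.
#' @param file optional output path; extension `.png` or `.svg` selects the
#'   device. `NULL` draws on the active device.
#' @param width,height device size in pixels (png) or inches (svg).
#' @param main overall title.
#' @return (invisibly) list with `panels` (group labels), `n_per_panel` and
#'   the colour mapping.
#' @export
seq_index_plot <- function(seqs, groups = NULL, file = NULL,
                           width = 900, height = 600, main = "Respiratory state sequences") {
  ids <- names(seqs)
  if (is.null(ids)) ids <- names(seqs) <- as.character(seq_along(seqs))
  if (is.null(groups)) groups <- stats::setNames(rep(1L, length(seqs)), ids)
  if (is.null(names(groups))) names(groups) <- ids
  groups <- groups[ids]
  cols <- state_colors()
  panels <- sort(unique(groups))

  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) {
      grDevices::svg(file, width = width / 100, height = height / 100)
    } else {
      grDevices::png(file, width = width, height = height)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  old_par <- graphics::par(mfrow = c(length(panels), 1L),
                           mar = c(2.5, 3.5, 2, 6), xpd = NA)
  on.exit(graphics::par(old_par), add = TRUE)
  max_len <- max(lengths(seqs))
  for (g in panels) {
    members <- ids[groups == g]
    members <- members[order(lengths(seqs[members]), decreasing = FALSE)]
    graphics::plot(NULL, xlim = c(0, max_len), ylim = c(0, length(members)),
                   xlab = "", ylab = "", yaxt = "n",
                   main = if (length(panels) > 1L) paste0(main, " - group ", g) else main,
                   cex.main = 0.9)
    graphics::mtext("seconds", side = 1, line = 1.6, cex = 0.7)
    for (j in seq_along(members)) {
      iv <- seq_to_intervals(seqs[[members[j]]])
      graphics::rect(iv$start_s, j - 1, iv$end_s, j - 0.1,
                     col = cols[iv$state], border = NA)
    }
    graphics::legend("right", inset = -0.12, legend = names(cols),
                     fill = cols, bty = "n", cex = 0.7)
  }
  invisible(list(panels = panels,
                 n_per_panel = as.integer(table(factor(groups, levels = panels))),
                 colors = cols))
}
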