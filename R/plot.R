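#' Multiplot grid of fitted melting curves
#'
#' Draws, for each requested protein, the four measured series (vehicle
#' and compound replicates) with their fitted LL4 curves overlaid, in a
#' grid for visual inspection of candidate hits. Vehicle curves are drawn
#' in blue, compound in red.
#'
#' @param dataset a (normalized) [melt_dataset()].
#' @param fits fit table from [fit_melt_curves()] covering the proteins.
#' @param proteins character vector of protein IDs to plot.
#' @param file optional PNG path; when given, the grid is written there
#'   instead of the active device.
#' @param ncol number of panel columns.
#' @return invisibly, the protein IDs plotted.
#' @export
plot_melt_curves <- function(dataset, fits, proteins, file = NULL,
                             ncol = 4) {
  stopifnot(inherits(dataset, "melt_dataset"))
  proteins <- intersect(proteins, dataset$protein_ids)
  if (!length(proteins)) stop("no matching proteins", call. = FALSE)
  nrow_grid <- ceiling(length(proteins) / ncol)
  if (!is.null(file)) {
    grDevices::png(file, width = 240 * ncol, height = 220 * nrow_grid)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(nrow_grid, ncol),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(old), add = TRUE)
  tt <- dataset$temperatures
  tfine <- seq(min(tt), max(tt), length.out = 100)
  for (pid in proteins) {
    graphics::plot(NA, xlim = range(tt),
                   ylim = c(0, max(1.2, dataset$values[pid, , ],
                                   na.rm = TRUE)),
                   xlab = "Temperature (°C)", ylab = "Fold change",
                   main = pid, cex.main = 0.9)
    graphics::abline(h = 0.5, col = "grey70", lty = 3)
    for (s in seq_len(nrow(dataset$samples))) {
      sid <- dataset$samples$sample_id[s]
      col <- if (dataset$samples$condition[s] == "vehicle") {
        "steelblue3"
      } else {
        "firebrick3"
      }
      graphics::points(tt, dataset$values[pid, sid, ], col = col,
                       pch = 16, cex = 0.7)
      row <- which(fits$protein_id == pid & fits$sample_id == sid)
      if (length(row) && fits$converged[row[1]]) {
        p <- ll4_params(fits$slope[row[1]], fits$lower[row[1]],
                        fits$upper[row[1]], fits$inflection[row[1]])
        graphics::lines(tfine, ll4_response(p, tfine), col = col)
      }
    }
  }
  invisible(proteins)
}
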