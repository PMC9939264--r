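# Minimal base-graphics diagnostics; publication graphics are out of scope.

#' Histogram of detected unit sizes
#'
#' @param result an [run_approach()] result.
#' @param ... passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot_unit_sizes <- function(result, ...) {
  stopifnot(inherits(result, "approach_result"))
  invisible(graphics::hist(result$size_distribution,
                           main = paste("Unit sizes:", format(result$config)),
                           xlab = "detected unit size", ...))
}

#' Stacked-band diagnostic of dynamic unit membership
#'
#' Draws, for each focal window, stacked bands whose heights are the
#' member counts of each global unit, with consistent vertical ordering,
#' giving a quick view of unit persistence, splits and merges over time.
#'
#' @param dyn a `dynamic_membership` object.
#' @return Invisibly, the per-window count table used for drawing.
#' @export
plot_membership_bands <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_membership"))
  a <- dyn$assignments
  tab <- table(a$global_unit, factor(a$window_id, levels = dyn$windows))
  n_win <- ncol(tab)
  graphics::plot(NULL, xlim = c(0.5, n_win + 0.5), ylim = c(0, max(colSums(tab)) * 1.05),
                 xaxt = "n", xlab = "focal window", ylab = "individuals",
                 main = "Dynamic unit membership")
  graphics::axis(1, at = seq_len(n_win), labels = colnames(tab), las = 2, cex.axis = 0.7)
  cols <- grDevices::hcl.colors(nrow(tab), "Dark 3")
  for (w in seq_len(n_win)) {
    y0 <- 0
    for (u in seq_len(nrow(tab))) {
      h <- tab[u, w]
      if (h > 0) {
        graphics::rect(w - 0.4, y0, w + 0.4, y0 + h, col = cols[u], border = NA)
        y0 <- y0 + h
      }
    }
  }
  invisible(tab)
}
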