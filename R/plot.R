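# colours of the blanket partition: hidden cyan, sensory magenta,
# active red, internal blue
partition_palette <- c(external = "cyan3", sensory = "magenta",
                       active = "red", internal = "blue")

# softmax of the three electrochemical states mapped to RGB
chem_colours <- function(chem) {
  e <- exp(chem - apply(chem, 1, max))
  s <- e / rowSums(e)
  grDevices::rgb(s[, 1], s[, 2], s[, 3])
}

#' Plot the ensemble
#'
#' Scatter of subsystem positions.  With no partition, points are
#' colour-coded by a softmax of the three electrochemical states mapped to
#' RGB (uniform states plot neutral grey); with a partition, the four
#' labels use the hidden/sensory/active/internal colour scheme (cyan,
#' magenta, red, blue).
#'
#' @param state an `ensemble_state`, or a `soup_trajectory` (its final
#'   frame is shown).
#' @param partition optional `blanket_partition`.
#' @param file optional output path (`.png` or `.svg`); plots to the
#'   current device when `NULL`.
#' @param main title.
#' @return the output path or `NULL`, invisibly.
#' @export
plot_ensemble <- function(state, partition = NULL, file = NULL,
                          main = "ensemble") {
  if (inherits(state, "soup_trajectory")) state <- state_at(state)
  p <- state$positions
  cols <- if (is.null(partition)) chem_colours(state$chem)
          else partition_palette[as.character(partition$labels)]
  open_dev(file)
  graphics::plot(p[, 1], p[, 2], pch = 19, col = cols, asp = 1,
                 xlab = "position x", ylab = "position y", main = main)
  if (!is.null(partition))
    graphics::legend("topright", legend = names(partition_palette),
                     col = partition_palette, pch = 19, cex = 0.8)
  close_dev(file)
}

open_dev <- function(file) {
  if (is.null(file)) return(invisible(NULL))
  if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 7)
  else grDevices::png(file, width = 900, height = 900, res = 130)
}

close_dev <- function(file) {
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' @export
plot.soup_trajectory <- function(x, partition = NULL, ...) {
  plot_ensemble(x, partition, main = sprintf("soup at t = %g s",
                                             x$times[length(x$times)]), ...)
}

#' @export
plot.blanket_partition <- function(x, state, ...) {
  plot_ensemble(state, partition = x, main = "Markov blanket partition", ...)
}

#' @export
plot.predictability_map <- function(x, file = NULL, ...) {
  open_dev(file)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); close_dev(file) })
  graphics::matplot(cbind(x$best_cva$actual, x$best_cva$predicted),
                    type = "l", lty = c(3, 1), col = 1,
                    xlab = "time (frames)", ylab = "canonical variate",
                    main = sprintf("best-predicted external subsystem #%d",
                                   x$best))
  graphics::legend("topright", c("actual", "predicted"), lty = c(3, 1),
                   cex = 0.8)
  br <- pretty(c(x$chi2_true, x$chi2_null), 20)
  h1 <- graphics::hist(x$chi2_true, breaks = br, plot = FALSE)
  h2 <- graphics::hist(x$chi2_null, breaks = br, plot = FALSE)
  graphics::barplot(rbind(h1$counts, h2$counts), beside = TRUE,
                    col = c("black", "white"),
                    names.arg = round(h1$mids, 1),
                    xlab = "chi-squared", ylab = "count",
                    main = sprintf("true (black) vs null (white); p = %.3g",
                                   x$p_value))
  invisible(x)
}
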