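#' Heatmap of a keyword co-occurrence matrix
#'
#' Draws the matrix with AI keywords on the vertical axis and biomedical
#' keywords on the horizontal axis, in their (dendrogram) order. With
#' `scale = "log"` the heat is `log10(1 + count)`. A matrix containing
#' negative values (a difference matrix) is drawn with a diverging
#' palette centered at 0. Optional dendrogram margins are drawn from the
#' axis merge trees.
#'
#' @param m numeric matrix (rows = AI keywords, columns = biomedical
#'   keywords), non-empty, with dimnames used as axis labels.
#' @param file output path; format from its extension (`.png` or `.svg`).
#' @param scale `"linear"` or `"log"`.
#' @param ai_tree,bio_tree optional `cluster_order` objects (or `hclust`)
#'   whose trees are drawn beside the heatmap.
#' @param main plot title.
#' @return `file`, invisibly.
#' @export
plot_heatmap <- function(m, file, scale = c("linear", "log"),
                         ai_tree = NULL, bio_tree = NULL, main = "") {
  scale <- match.arg(scale)
  if (length(m) == 0) stop("empty matrix")
  diverging <- any(m < 0)
  z <- if (scale == "log" && !diverging) log_heat(m) else m
  open_device(file, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  tree_of <- function(x) if (inherits(x, "cluster_order")) x$hclust else x
  at <- tree_of(ai_tree); bt <- tree_of(bio_tree)
  if (!is.null(at) || !is.null(bt)) {
    graphics::layout(matrix(c(4, 2, 3, 1), 2, 2),
                     widths = c(1, 4), heights = c(1, 4))
  }
  if (diverging) {
    lim <- max(abs(z))
    pal <- grDevices::hcl.colors(64, "Blue-Red 2")
    brk <- seq(-lim, lim, length.out = 65)
  } else {
    pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
    brk <- seq(min(z), max(z) + 1e-9, length.out = 65)
  }
  graphics::par(mar = c(6, 6, 2, 1))
  # image() draws row 1 at the bottom; flip so row 1 is on top
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)),
                  t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = pal, breaks = brk, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(ncol(z)), labels = colnames(z) %||% seq_len(ncol(z)),
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(z)), labels = rev(rownames(z) %||% seq_len(nrow(z))),
                 las = 2, cex.axis = 0.6)
  graphics::box()
  if (!is.null(at) || !is.null(bt)) {
    if (!is.null(bt)) {
      graphics::par(mar = c(0, 6, 1, 1))
      graphics::plot(stats::as.dendrogram(bt), leaflab = "none",
                     axes = FALSE, xaxs = "i")
    } else graphics::plot.new()
    if (!is.null(at)) {
      graphics::par(mar = c(6, 0, 1, 0))
      graphics::plot(stats::as.dendrogram(at), leaflab = "none",
                     axes = FALSE, horiz = TRUE, yaxs = "i")
    } else graphics::plot.new()
  }
  invisible(file)
}

#' Line plot of per-bin R-squared traces
#'
#' One line per forecast run; gaps (bins without actuals) are left
#' unconnected rather than interpolated.
#'
#' @param runs a `forecast_run` or list of them, at least one with a
#'   non-empty trace.
#' @param file output path (`.png` or `.svg`).
#' @return `file`, invisibly.
#' @export
plot_r2_trace <- function(runs, file) {
  if (inherits(runs, "forecast_run")) runs <- list(runs)
  traces <- lapply(runs, `[[`, "r2_trace")
  if (all(vapply(traces, length, integer(1)) == 0))
    stop("all R^2 traces are empty")
  open_device(file, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  all_bins <- unique(unlist(lapply(traces, names)))
  ylim <- range(unlist(traces), finite = TRUE)
  graphics::plot(NA, xlim = c(1, length(all_bins)), ylim = ylim,
                 xaxt = "n", xlab = "time bin", ylab = expression(R^2))
  graphics::axis(1, at = seq_along(all_bins), labels = all_bins, las = 2,
                 cex.axis = 0.7)
  cols <- grDevices::hcl.colors(max(2, length(runs)), "Dark 3")
  for (k in seq_along(runs)) {
    tr <- traces[[k]]
    if (length(tr) == 0) next
    x <- match(names(tr), all_bins)
    graphics::lines(x, tr, col = cols[k], type = "b", pch = 16)
  }
  graphics::legend("bottomleft", bty = "n", col = cols[seq_along(runs)],
                   lty = 1, pch = 16,
                   legend = vapply(runs, function(r)
                     sprintf("%s w=%d", r$backend, r$w), character(1)))
  invisible(file)
}

#' Scatter plot of a 2-D embedding projection
#'
#' @param coords matrix from [project_2d()] (rownames = terms).
#' @param file output path.
#' @param labels draw term labels (default `TRUE`).
#' @param col point colors (e.g. cluster labels).
#' @return `file`, invisibly.
#' @export
plot_projection <- function(coords, file, labels = TRUE, col = 1) {
  open_device(file, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  graphics::plot(coords[, 1], coords[, 2], pch = 16, col = col,
                 xlab = "dim 1", ylab = "dim 2")
  if (labels)
    graphics::text(coords[, 1], coords[, 2], rownames(coords),
                   pos = 3, cex = 0.6)
  invisible(file)
}

open_device <- function(file, width, height) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = grDevices::png(file, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(file, width = width, height = height),
    stop("unsupported plot format '.", ext, "' (use .png or .svg)")
  )
}
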