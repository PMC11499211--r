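# Base-graphics visualizations: network graph (node size ~ occurrence, edge
# width ~ transition weight) and transition heat map (white -> red).

#' Plot a behavior transition network
#'
#' `type = "graph"` draws the directed network on a circular layout with node
#' area proportional to mean occurrence count and arrow width proportional to
#' transition weight. `type = "heatmap"` draws the 6x6 weight matrix with a
#' white-to-red scale (white = lowest weight, red = highest).
#'
#' @param x A `beh_network`.
#' @param type `"graph"` or `"heatmap"`.
#' @param ... Further arguments passed to the underlying graphics calls.
#' @return `x`, invisibly.
#' @export
plot.beh_network <- function(x, type = c("graph", "heatmap"), ...) {
  type <- match.arg(type)
  ctx <- x$context
  main <- sprintf("%s, %s phase, PPD %d", ctx$group, ctx$phase, ctx$ppd)
  if (type == "heatmap") {
    w <- x$weights
    pal <- grDevices::colorRampPalette(c("white", "#fddbc7", "#ef8a62",
                                         "#b2182b"))(100)
    hi <- max(w, 1e-9)
    graphics::image(seq_len(6), seq_len(6), t(w[rev(seq_len(6)), ]),
                    col = pal, zlim = c(0, hi), axes = FALSE,
                    xlab = "to", ylab = "from", main = main, ...)
    graphics::axis(1, at = seq_len(6), labels = colnames(w), las = 2)
    graphics::axis(2, at = seq_len(6), labels = rev(rownames(w)), las = 2)
    graphics::box()
    return(invisible(x))
  }
  n <- length(x$nodes)
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  px <- cos(theta)
  py <- sin(theta)
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main, ...)
  wmax <- max(x$weights, 1e-9)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- x$weights[i, j]
    if (w <= 0) next
    # shorten the arrow so it stops at the node circle, offset a touch so
    # reciprocal edges do not overlap
    dx <- px[j] - px[i]; dy <- py[j] - py[i]
    len <- sqrt(dx^2 + dy^2)
    ox <- -dy / len * 0.04; oy <- dx / len * 0.04
    shrink <- 0.16
    graphics::arrows(px[i] + dx / len * shrink + ox,
                     py[i] + dy / len * shrink + oy,
                     px[j] - dx / len * shrink + ox,
                     py[j] - dy / len * shrink + oy,
                     lwd = 0.5 + 4 * w / wmax, length = 0.1,
                     col = grDevices::grey(0.25))
  }
  smax <- max(x$node_sizes, 1e-9)
  cols <- grDevices::hcl.colors(n, "Dark 3")
  graphics::symbols(px, py, circles = 0.05 + 0.12 * sqrt(x$node_sizes / smax),
                    inches = FALSE, add = TRUE, bg = cols, fg = "black")
  graphics::text(px * 1.3, py * 1.3, labels = x$nodes, font = 2)
  invisible(x)
}
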