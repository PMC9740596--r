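# Percentile-based rendering of sensitivity matrices, following the
# published green-to-red scheme: class boundaries at the 50th / 75th /
# 90th / 97.5th percentile of the whole matrix.

.color_classes <- c("green", "yellow", "orange", "orangered", "red")

#' Percentile color classes for a sensitivity matrix
#'
#' Assigns each cell a class from its percentile rank (fraction of cells
#' strictly below it) within the whole matrix: green below the median,
#' then yellow / orange / orangered / red at the 50th / 75th / 90th /
#' 97.5th percentile.  Also flags columns whose every entry exceeds the
#' matrix median — the published marker for uniformly sensitive outputs.
#'
#' @param S numeric matrix of first-order indices (parameters x outputs),
#'   finite, entries in \[0, 1\].
#' @param breaks percentile class boundaries.
#' @return A list with `classes` (character matrix like `S`),
#'   `above_median_columns` (logical per column) and `breaks`.
#' @examples
#' S <- matrix(runif(20), 5, 4)
#' percentile_colorcode(S)$classes
#' @export
percentile_colorcode <- function(S, breaks = c(0.5, 0.75, 0.9, 0.975)) {
  S <- as.matrix(S)
  if (length(S) == 0) stop("empty matrix")
  if (!all(is.finite(S))) stop("matrix must be finite")
  if (any(S < 0 | S > 1)) stop("indices must lie in [0, 1]")
  v <- sort(as.vector(S))
  n <- length(v)
  rank_below <- matrix(findInterval(S, v, left.open = TRUE) / n, nrow(S),
                       dimnames = dimnames(S))
  cls <- matrix(.color_classes[findInterval(rank_below, breaks) + 1L],
                nrow(S), dimnames = dimnames(S))
  med <- stats::median(S)
  list(classes = cls,
       above_median_columns = apply(S > med, 2, all),
       breaks = breaks)
}

#' Heatmap of a sensitivity matrix in the published layout
#'
#' Base-graphics heatmap with parameters as rows (heatmap row order) and
#' outputs as columns, colored by [percentile_colorcode()] classes.
#'
#' @param S numeric matrix (parameters x outputs).
#' @param main title.
#' @export
plot_sensitivity_heatmap <- function(S, main = "first-order FAST indices") {
  cc <- percentile_colorcode(S)
  idx <- matrix(match(cc$classes, .color_classes), nrow(S))
  old <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit(graphics::par(old))
  graphics::image(seq_len(ncol(S)), seq_len(nrow(S)), t(idx[rev(seq_len(nrow(S))), ]),
                  col = .color_classes, zlim = c(1, length(.color_classes)),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_len(ncol(S)), colnames(S), las = 2, cex.axis = 0.5)
  graphics::axis(2, seq_len(nrow(S)), rev(rownames(S)), las = 2, cex.axis = 0.4)
  invisible(cc)
}

#' @export
plot.fast_result <- function(x, t = x$t_points[1],
                             what = c("metabolites", "reactions"), ...) {
  what <- match.arg(what)
  k <- match(t, x$t_points)
  if (is.na(k)) stop("t must be one of the analysed horizons")
  plot_sensitivity_heatmap(x$indices[[k]][[what]],
                           main = sprintf("%s, t = %g min", what, t))
}
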