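#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_line
#'   geom_hline geom_errorbar facet_grid labs scale_fill_manual theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot confidence sets as a nesting label map
#'
#' Renders a 2D lattice (or one slice of a 3D lattice) with the lower set,
#' point-estimate set and upper set overlaid; the band between the upper and
#' lower sets is the simultaneous confidence region for the true excursion
#' boundary.
#'
#' @param object a `cs_confidence_sets`.
#' @param slice slice index along the third axis (3D only; defaults to the
#'   middle slice).
#' @param ... unused.
#' @returns a ggplot.
#' @export
autoplot.cs_confidence_sets <- function(object, slice = NULL, ...) {
  lab <- cs_label_map(object)
  msk <- object$mask
  if (length(object$dim) == 3L) {
    if (is.null(slice)) slice <- ceiling(object$dim[3L] / 2)
    lab <- lab[, , slice]
    msk <- msk[, , slice]
  }
  d <- dim(lab)
  df <- data.frame(
    x = rep(seq_len(d[1L]), times = d[2L]),
    y = rep(seq_len(d[2L]), each = d[1L]),
    label = factor(ifelse(as.vector(msk), as.vector(lab), NA),
                   levels = 0:3,
                   labels = c("outside", "lower only", "point estimate",
                              "upper"))
  )
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$label)) +
    geom_tile() +
    scale_fill_manual(values = c(outside = "grey90", `lower only` = "#4477AA",
                                 `point estimate` = "#DDCC77",
                                 upper = "#CC3311"),
                      na.value = "white", drop = FALSE) +
    labs(fill = NULL,
         title = sprintf("Confidence sets for {contrast ≥ %g}, k = %.3g",
                         object$c, object$k)) +
    theme_minimal()
}

#' @export
plot.cs_confidence_sets <- function(x, ...) print(autoplot(x, ...))

#' Plot an empirical coverage table
#'
#' Coverage against sample size, one panel per significance level, coloured
#' by bootstrap method and assessment, with the nominal level and binomial
#' Monte-Carlo error bars.
#'
#' @param tab a `cs_coverage_table` (see [run_simulation()]), or several
#'   row-bound together.
#' @returns a ggplot.
#' @export
plot_coverage <- function(tab) {
  stopifnot(is.data.frame(tab))
  tab$method <- paste(tab$multiplier, tab$variant, tab$boundary,
                      tab$assessment, sep = "/")
  ggplot(tab, aes(x = .data$n, y = .data$coverage, colour = .data$method)) +
    geom_hline(aes(yintercept = 1 - .data$alpha), linetype = 2) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$coverage - .data$mc_halfwidth,
                      ymax = .data$coverage + .data$mc_halfwidth),
                  width = 0.02 * max(tab$n)) +
    facet_grid(cols = ggplot2::vars(.data$alpha),
               labeller = ggplot2::label_both) +
    labs(x = "subjects per trial", y = "empirical coverage", colour = NULL) +
    theme_minimal()
}
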