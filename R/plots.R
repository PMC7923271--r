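# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a partitioned composition report
#'
#' Dot plot of A+T percentage (or a skew) per partition, grouped by
#' partition type.
#'
#' @param report Tibble from [partitioned_composition()] (rows from several
#'   genomes may be combined).
#' @param metric One of `at_percent`, `at_skew`, `gc_skew`.
#' @return A ggplot.
#' @export
plot_composition <- function(report, metric = c("at_percent", "at_skew",
                                                "gc_skew")) {
  metric <- match.arg(metric)
  ggplot(report, aes(x = .data$partition, y = .data[[metric]],
                     colour = .data$strand)) +
    geom_point(position = position_jitter(width = 0.1, height = 0), alpha = 0.8) +
    facet_grid(cols = vars(.data$partition_type), scales = "free_x",
               space = "free_x") +
    labs(x = NULL, y = metric, colour = "strand") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Bar chart of substitution-type tallies by branch class
#'
#' @param object A `cbc_tally` from [tally_cbc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cbc_tally
#' @export
autoplot.cbc_tally <- function(object, ...) {
  d <- object$type[object$type$category %in% c("FCBC", "HCBC"), ]
  ggplot(d, aes(x = stats::reorder(.data$change, -.data$events),
                y = .data$events, fill = .data$branch_class)) +
    geom_col(position = "dodge") +
    facet_wrap(vars(.data$category), scales = "free_x") +
    labs(x = "substitution type", y = "events", fill = "branch class") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Per-site Z-score track for the radical magnitude categories
#'
#' @param object A `z_report` from [z_scan()].
#' @param ... Unused.
#' @return A ggplot with the significance threshold line.
#' @method autoplot z_report
#' @export
autoplot.z_report <- function(object, ...) {
  if (!nrow(object$site)) {
    return(ggplot() + labs(title = "no substitutions scored") + theme_bw())
  }
  ggplot(object$site, aes(x = .data$site, y = .data$z,
                          colour = factor(.data$category))) +
    geom_line() +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    facet_wrap(vars(.data$property)) +
    labs(x = "codon site (window start)", y = "Z", colour = "category") +
    theme_bw()
}

#' Tanglegram line plot of matched leaves
#'
#' @param object A `tanglegram` from [tanglegram_export()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tanglegram
#' @export
autoplot.tanglegram <- function(object, ...) {
  d <- object$leaves
  ggplot(d) +
    geom_segment(aes(x = 1, xend = 2, y = .data$pos1, yend = .data$pos2)) +
    geom_text(aes(x = 0.97, y = .data$pos1, label = .data$taxon), hjust = 1) +
    geom_text(aes(x = 2.03, y = .data$pos2, label = .data$taxon), hjust = 0) +
    scale_x_continuous(limits = c(0.5, 2.5), breaks = NULL) +
    labs(x = NULL, y = NULL,
         title = sprintf("%d crossing(s)", object$crossings)) +
    theme_minimal() +
    theme(axis.text.y = element_blank())
}
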