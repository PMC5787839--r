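#' Plot a metagene or TE methylation profile
#'
#' Line plot of the binned, count-pooled methylation level per context
#' along the fixed feature axis, with segment boundaries marked. Requires
#' ggplot2.
#'
#' @param profile a profile table from [metagene_profile()] or
#'   [te_profile()], or a named list of them (one line set per group).
#' @return a ggplot object.
#' @export
plot_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  dt <- if (data.table::is.data.table(profile)) {
    data.table::copy(profile)[, group := "all"]
  } else {
    data.table::rbindlist(profile, idcol = "group")
  }
  breaks <- dt[, .(b = max(bin)), by = segment]$b
  ggplot2::ggplot(dt, ggplot2::aes(x = bin, y = ml, colour = group)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~context, ncol = 1, scales = "free_y") +
    ggplot2::geom_vline(xintercept = utils::head(breaks, -1) + 0.5,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "feature axis (binned)",
                  y = "methylation level (count-pooled)") +
    ggplot2::theme_minimal()
}
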