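#' Plot per-spot cell-type proportions in space
#'
#' One panel per cell type, spots coloured by inferred proportion — the
#' standard way deconvolution results are inspected against anatomy.
#'
#' @param props N x T proportion matrix.
#' @param coords [spot_coords()] for the same spots.
#' @param types subset of cell types to show (default: all).
#' @param point_size point size passed to `geom_point`.
#' @return a ggplot object.
#' @export
plot_proportions <- function(props, coords, types = colnames(props),
                             point_size = 0.8) {
  stopifnot(nrow(props) == nrow(coords$xy))
  df <- do.call(rbind, lapply(types, function(ct) {
    data.frame(x = coords$xy[, 1], y = coords$xy[, 2],
               proportion = props[, ct], cell_type = ct)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$proportion)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "proportion")
}

#' Plot training loss history
#'
#' @param fit a `spotsparse_fit`.
#' @return a ggplot object with one line per loss component.
#' @export
plot_loss <- function(fit) {
  h <- fit$history
  comps <- c("total", "recon", "kl", "supervised")
  df <- do.call(rbind, lapply(comps, function(cc) {
    data.frame(epoch = h$epoch, loss = h[[cc]], component = cc)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.spotsparse_fit <- function(object, ...) plot_loss(object)
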