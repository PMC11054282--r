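#' Plot a titration profile
#'
#' Mean IFP_CS per rung against rung temperature, with the endpoint chord
#' whose slope is the MS coefficient drawn through the first and last
#' points.
#'
#' @param profile a `titration_profile`.
#' @return a ggplot object.
#' @export
plot_titration_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_titration_profile requires ggplot2")
  df <- as.data.frame(profile)
  ends <- df[c(1, nrow(df)), ]
  ms <- attr(profile, "ms_coefficient")
  ggplot2::ggplot(df, ggplot2::aes(x = temperature,
                                   y = mean_ifp_cs)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_line(data = ends, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "temperature (K)", y = "mean IFP_CS",
                  title = sprintf("titration profile (MS = %.4g / K)", ms)) +
    ggplot2::ylim(-1, 0)
}

#' Plot a per-site electrostatic interaction heat map
#'
#' Time on the x-axis, the most contacted sites on the y-axis, tile colour
#' from blue (negative, stabilizing) to red (positive).
#'
#' @param mat matrix from [per_residue_ele_heatmap()].
#' @return a ggplot object.
#' @export
plot_ele_heatmap <- function(mat) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ele_heatmap requires ggplot2")
  df <- data.frame(site = factor(rep(rownames(mat), ncol(mat)),
                                 levels = rev(rownames(mat))),
                   frame = rep(seq_len(ncol(mat)), each = nrow(mat)),
                   ele = as.vector(mat))
  lim <- max(abs(df$ele))
  ggplot2::ggplot(df, ggplot2::aes(x = frame, y = site,
                                   fill = ele)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-lim, lim)) +
    ggplot2::labs(x = "frame", y = NULL, fill = "IEele\n(kcal/mol)")
}
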