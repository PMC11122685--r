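# ggplot2 views of each result type. These return plot objects; nothing is
# drawn or written as a side effect.

#' Plot a per-subdomain RMSD series
#'
#' @param series Output of [rmsd_series()].
#' @return A ggplot.
#' @export
plot_rmsd_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame, y = .data$rmsd,
                                       colour = .data$subdomain)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Frame", y = "RMSD (Å)", colour = "Subdomain") +
    ggplot2::theme_minimal()
}

#' Plot an RMSF difference profile (mutant - wild type style)
#'
#' @param delta Output of [delta_rmsf()].
#' @return A ggplot.
#' @export
plot_delta_rmsf <- function(delta) {
  ggplot2::ggplot(delta, ggplot2::aes(x = .data$resno, y = .data$delta_rmsf)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "Residue", y = expression(Delta * "RMSF (Å)")) +
    ggplot2::theme_minimal()
}

dccm_to_long <- function(m) {
  keys <- attr(m, "keys")
  g <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  tibble(i = g$i, j = g$j, key_i = keys[g$i], key_j = keys[g$j],
         value = as.numeric(unclass(m)[cbind(g$i, g$j)]))
}

#' Heatmap of a cross-correlation matrix or difference map
#'
#' @param m A `dccm` or `dccm_diff` object.
#' @return A ggplot.
#' @export
plot_dccm <- function(m) {
  long <- dccm_to_long(m)
  lim <- if (inherits(m, "dccm")) c(-1, 1) else {
    mx <- max(abs(long$value), na.rm = TRUE); c(-mx, mx)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$i, y = .data$j,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = lim) +
    ggplot2::labs(x = "Residue index", y = "Residue index",
                  fill = if (inherits(m, "dccm")) "C_ij" else "ΔC_ij") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Scatter plot of a clustering result with the competence box
#'
#' @param object A `competence_clusters` from [kmeans_2d()].
#' @param box A [competence_box()] drawn as an overlay (or `NULL`).
#' @param max_points Subsample cap for plotting speed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot competence_clusters
#' @export
autoplot.competence_clusters <- function(object, box = competence_box(),
                                         max_points = 20000L, ...) {
  pts <- tibble(d1 = object$points[, 1], d2 = object$points[, 2],
                cluster = factor(object$assignment))
  if (nrow(pts) > max_points) {
    keep <- seq(1L, nrow(pts), length.out = max_points)
    pts <- pts[keep, ]
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$d1, y = .data$d2,
                                         colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_point(data = object$centroids,
                        ggplot2::aes(x = .data$d1, y = .data$d2),
                        colour = "black", shape = 4, size = 3,
                        inherit.aes = FALSE) +
    ggplot2::labs(x = "d1: primer O3' – Pα (Å)",
                  y = "d2: Asp – primer O3' (Å)",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
  if (!is.null(box)) {
    p <- p + ggplot2::annotate("rect", xmin = box$d1_min, xmax = box$d1_max,
                               ymin = box$d2_min, ymax = box$d2_max,
                               fill = NA, colour = "black",
                               linetype = "dashed")
  }
  p
}

#' Bar chart of an energy-decomposition profile with SEM error bars
#'
#' @param profile Output of [eda_profile()].
#' @param top_n Show only the `top_n` largest |total| contributors
#'   (`NULL` for all).
#' @return A ggplot.
#' @export
plot_eda_profile <- function(profile, top_n = NULL) {
  df <- profile
  if (!is.null(top_n)) {
    df <- df[order(-abs(df$total_mean)), , drop = FALSE]
    df <- head(df, top_n)
  }
  long <- tidyr::pivot_longer(
    df, c("coulomb_mean", "vdw_mean"),
    names_to = "term", values_to = "energy")
  long$sem <- ifelse(long$term == "coulomb_mean", long$coulomb_sem,
                     long$vdw_sem)
  long$term <- ifelse(long$term == "coulomb_mean", "Coulomb", "van der Waals")
  long$label <- paste0(long$resname, long$resno)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$energy,
                                     fill = .data$term)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$energy - .data$sem,
                   ymax = .data$energy + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Interaction energy (kcal/mol)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Isotherm plot: measured and fitted per-injection heats vs molar ratio
#'
#' @param object A `binding_fit` from [fit_isotherm()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  tb <- tidy(object$isotherm)
  tb$fitted <- object$fitted
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat_ucal)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Molar ratio (ligand/macromolecule)",
                  y = "Heat per injection (µcal)") +
    ggplot2::theme_minimal()
}
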