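# Figures --------------------------------------------------------------------

#' Genotype trajectory plot with SEM bands
#'
#' Mean curve per genotype with a +/- SEM ribbon, replicate counts in the
#' legend, and reference lines at time zero and the analysis cutoff.
#'
#' @param table wide modality table.
#' @param ylab y-axis label (modality and units).
#' @param tmax optional cutoff drawn as a vertical reference line.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(table, ylab = "Mean climbing height (cm)",
                              tmax = NULL) {
  cur <- genotype_curves(table)
  nmax <- tapply(cur$n, cur$genotype, max)
  cur$genotype <- sprintf("%s (N=%d)", cur$genotype,
                          nmax[as.character(cur$genotype)])
  p <- ggplot2::ggplot(cur, ggplot2::aes(x = time_s, y = mean,
                                         colour = genotype,
                                         fill = genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem,
                                      ymax = mean + sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Time (s)", y = ylab, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(tmax) && is.finite(tmax))
    p <- p + ggplot2::geom_vline(xintercept = tmax, linetype = "dashed",
                                 colour = "grey40")
  p
}

#' Bar plot of -log10 harmonic-mean p-values
#'
#' One bar per modality for a single comparison genotype, with the p = 0.05
#' reference line.
#'
#' @param report a [comparison_report()] result.
#' @param comparison comparison genotype name.
#' @return a ggplot object.
#' @export
plot_hmp_bars <- function(report, comparison) {
  pv <- report$pvalues[[comparison]]
  lme_names <- grep("_LME$", names(pv), value = TRUE)
  df <- data.frame(metric = sub("_LME$", "", lme_names),
                   neglog10_p = -log10(unlist(pv[lme_names])))
  ggplot2::ggplot(df, ggplot2::aes(x = metric,
                                   y = neglog10_p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = paste("LME harmonic-mean p:", comparison)) +
    ggplot2::theme_minimal()
}

#' Heatmap of time-resolved Mann-Whitney significance
#'
#' Tiles of `-log10(p)` over time for one or more comparisons; high
#' significance renders as the intense end of the gradient.
#'
#' @param grids named list of [mwu_timepoints()] outputs (names label rows).
#' @return a ggplot object.
#' @export
plot_mwu_heatmap <- function(grids) {
  df <- do.call(rbind, lapply(names(grids), function(nm) {
    g <- grids[[nm]]
    if (is.null(g)) return(NULL)
    data.frame(comparison = nm, time_s = g$time_s,
               neglog10_p = g$neglog10_p)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = time_s, y = comparison,
                                   fill = neglog10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "lemonchiffon", high = "red3",
                                 name = expression(-log[10](p))) +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write the report's figure panels as PNGs
#'
#' @param report a [comparison_report()] result.
#' @param tables the modality tables the report was built from.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
save_report_figures <- function(report, tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save1 <- function(plot, name) {
    p <- file.path(dir, name)
    ggplot2::ggsave(p, plot, width = 7, height = 4, dpi = 120)
    paths <<- c(paths, p)
  }
  save1(plot_trajectories(tables$position, tmax = report$tmax),
        "trajectory_position.png")
  for (g in report$comparisons) {
    save1(plot_hmp_bars(report, g),
          sprintf("hmp_bars_%s.png", gsub("[^A-Za-z0-9_]", "_", g)))
  }
  pos_grids <- report$mwu_grids[grep("^position\\.",
                                     names(report$mwu_grids))]
  names(pos_grids) <- sub("^position\\.", "", names(pos_grids))
  if (length(pos_grids))
    save1(plot_mwu_heatmap(pos_grids), "mwu_heatmap_position.png")
  invisible(paths)
}
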