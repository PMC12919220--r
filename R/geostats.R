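# Statistical layer ----------------------------------------------------------
#
# Genotype x time linear mixed-effects models with per-subject random
# intercepts and time slopes (REML, Wald z tests), harmonic-mean p-value
# combination of each comparison genotype's main effect + interaction
# p-values, and Mann-Whitney U tests both per time point (-log10(p)
# heatmaps) and on per-replicate peak metrics.

#' Long-form table for the mixed model
#'
#' Melts a wide modality table into rows `(genotype, replicate, time,
#' value, subject)`, keeping only the control and comparison genotypes and
#' observations with `time <= tmax`. The genotype factor has the control as
#' reference level; time is carried both numerically (`time`, the random
#' slope) and categorically (`time_cat`, the fixed effect).
#'
#' @param table wide modality table (`replicate` column + time columns).
#' @param control control genotype name (must be present).
#' @param comparisons character vector of comparison genotype names.
#' @param tmax time cutoff in seconds.
#' @return long data.frame; the control name is attached as
#'   `attr(, "control")`.
#' @export
build_long_table <- function(table, control, comparisons, tmax = Inf) {
  if (control %in% comparisons)
    stop_geotax("control genotype cannot also be a comparison")
  genos <- sub("_rep[0-9]+$", "", table$replicate)
  if (!control %in% genos)
    stop_geotax("control genotype '%s' absent from table", control)
  keep <- genos %in% c(control, comparisons)
  tab <- table[keep, , drop = FALSE]
  genos <- genos[keep]
  times <- table_times(tab)
  tsel <- times <= tmax
  if (!any(tsel)) stop_geotax("no observations with time <= %g", tmax)
  long <- do.call(rbind, lapply(seq_len(nrow(tab)), function(r) {
    data.frame(genotype = genos[r],
               replicate = sub("^.*_rep", "", tab$replicate[r]),
               subject = tab$replicate[r],
               time = times[tsel],
               value = as.numeric(tab[r, -1])[tsel])
  }))
  long <- long[!is.na(long$value), ]
  if (nrow(long) == 0L) stop_geotax("long table is empty after filtering")
  long$genotype <- stats::relevel(factor(long$genotype), ref = control)
  long$time_cat <- factor(long$time)
  attr(long, "control") <- control
  long
}

#' Fit the genotype x time mixed-effects model
#'
#' `value ~ genotype * time_cat + (1 + time | subject)`, fitted by REML.
#' Genotype is treatment-coded against the control; time enters the fixed
#' effects categorically and the per-subject random structure numerically
#' (random intercept + time slope). Wald p-values (`2 * pnorm(-|est/se|)`)
#' are extracted for every fixed effect; for each comparison genotype the
#' main-effect and interaction p-values are combined with
#' [harmonic_mean_p()] and star-annotated. Singular or non-converged fits
#' are flagged, not fatal.
#'
#' @param long output of [build_long_table()].
#' @return a `geotax_lme` list: `coefficients` (term, estimate, se, z, p),
#'   `genotypes` (genotype, hmp, stars, n_terms), `varcor`, `converged`,
#'   `singular`, and the underlying `model`.
#' @export
fit_lme <- function(long) {
  if (length(unique(long$time)) < 2L)
    stop_geotax("need >= 2 time points")
  per_geno <- tapply(long$subject, long$genotype,
                     function(s) length(unique(s)))
  if (any(per_geno < 2L, na.rm = TRUE))
    stop_geotax("need >= 2 subjects per genotype")
  msgs <- character(0)
  model <- withCallingHandlers(
    lme4::lmer(value ~ genotype * time_cat + (1 + time | subject),
               data = long, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  est <- lme4::fixef(model)
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(model)))),
                 error = function(e) {
                   msgs <<- c(msgs, conditionMessage(e))
                   rep(NA_real_, length(est))
                 })
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = names(est), estimate = as.numeric(est),
                      se = as.numeric(se), z = as.numeric(z),
                      p = as.numeric(p), row.names = NULL)
  comparisons <- setdiff(levels(long$genotype), attr(long, "control"))
  genos <- do.call(rbind, lapply(comparisons, function(g) {
    main <- paste0("genotype", g)
    inter <- grep(paste0("^genotype", g, ":time_cat"), coefs$term,
                  value = TRUE)
    ps <- coefs$p[coefs$term %in% c(main, inter)]
    hmp <- if (any(is.na(ps))) NA_real_ else harmonic_mean_p(ps)
    data.frame(genotype = g, hmp = hmp,
               stars = if (is.na(hmp)) NA_character_
               else star_annotation(hmp),
               n_terms = length(ps))
  }))
  structure(list(model = model, coefficients = coefs, genotypes = genos,
                 varcor = lme4::VarCorr(model),
                 singular = lme4::isSingular(model),
                 converged = length(msgs) == 0L, messages = msgs),
            class = "geotax_lme")
}

#' @export
print.geotax_lme <- function(x, ...) {
  cat("Genotype x time LME (REML, Wald z)\n")
  if (x$singular) cat("  [flagged: singular fit]\n")
  if (!x$converged) cat("  [flagged: convergence messages]\n")
  print(x$genotypes)
  invisible(x)
}

#' Significance stars
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `NS`
#' above; thresholds inclusive. Vectorised; p outside `[0, 1]` is an error.
#'
#' @param p p-value(s).
#' @return character vector of annotations.
#' @export
star_annotation <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_geotax("p-values must lie in [0, 1]")
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "NS")))
}

#' Harmonic mean p-value
#'
#' Combines `r` (possibly dependent) p-values as
#' `min(1, r / sum(1 / (p_i + eps)))`; `eps` guards the `p_i = 0`
#' reciprocal. Equal inputs return that value; the combination is
#' conservative for dependent tests.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param epsilon tiny positive guard constant.
#' @return the combined p-value.
#' @export
harmonic_mean_p <- function(pvalues, epsilon = 1e-12) {
  if (length(pvalues) == 0L) stop_geotax("no p-values to combine")
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop_geotax("p-values must lie in [0, 1]")
  min(1, length(pvalues) / sum(1 / (pvalues + epsilon)))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when the combined sample size is at most
#' `exact_max_n` and there are no ties; otherwise the normal approximation
#' with continuity and tie correction. All-identical inputs return p = 1 by
#' convention.
#'
#' @param x,y numeric group samples.
#' @param exact_max_n combined-n ceiling for the exact test (default 20).
#' @return list with `statistic` (U for the first group) and `p`.
#' @export
mwu_test <- function(x, y, exact_max_n = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop_geotax("both groups need at least one observation")
  u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    message("all values identical; Mann-Whitney p set to 1")
    return(list(statistic = u, p = 1))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= exact_max_n && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = as.numeric(wt$statistic), p = wt$p.value)
}

#' Time-resolved Mann-Whitney grid
#'
#' A two-sided U test between the control and comparison replicate values
#' at every time point, with the `-log10(p)` transform used for heatmaps.
#'
#' @param table wide modality table.
#' @param control,comparison genotype names.
#' @param tmax time cutoff in seconds.
#' @return data.frame `time_s, p, neglog10_p`.
#' @export
mwu_timepoints <- function(table, control, comparison, tmax = Inf) {
  genos <- sub("_rep[0-9]+$", "", table$replicate)
  times <- table_times(table)
  sel <- which(times <= tmax)
  rows <- lapply(sel, function(j) {
    x <- as.numeric(table[genos == control, j + 1])
    y <- as.numeric(table[genos == comparison, j + 1])
    p <- suppressMessages(mwu_test(x, y)$p)
    data.frame(time_s = times[j], p = p, neglog10_p = -log10(p))
  })
  do.call(rbind, rows)
}

#' Per-replicate peak metrics and their group comparison
#'
#' `peak_metrics` takes each replicate's maximum over `time <= tmax`;
#' `mwu_peaks` compares the control and comparison peak sets with
#' [mwu_test()].
#'
#' @param table wide modality table.
#' @param tmax time cutoff in seconds.
#' @return `peak_metrics`: data.frame `replicate, genotype, peak`.
#' @export
peak_metrics <- function(table, tmax = Inf) {
  times <- table_times(table)
  sel <- times <= tmax
  if (!any(sel)) stop_geotax("no time points <= %g", tmax)
  data.frame(replicate = table$replicate,
             genotype = sub("_rep[0-9]+$", "", table$replicate),
             peak = apply(table[, -1, drop = FALSE][, sel, drop = FALSE],
                          1, function(v) max(v, na.rm = TRUE)))
}

#' @rdname peak_metrics
#' @param control,comparison genotype names.
#' @return `mwu_peaks`: list with `p`, `statistic` and the `peaks` table.
#' @export
mwu_peaks <- function(table, control, comparison, tmax = Inf) {
  pk <- peak_metrics(table, tmax)
  res <- suppressMessages(
    mwu_test(pk$peak[pk$genotype == control],
             pk$peak[pk$genotype == comparison]))
  list(p = res$p, statistic = res$statistic, peaks = pk)
}

#' Full comparison report across the five modalities
#'
#' For each modality: the LME fit (HMP per comparison genotype) and the
#' peak Mann-Whitney test, assembled into the assay's standard 10-row
#' results table (`<modality>_LME` and `<modality>_Peak` rows, one column
#' per comparison, cells `"p (stars)"`), plus machine-readable p-values and
#' the per-time-point Mann-Whitney grids for heatmaps. A missing or
#' unfittable modality leaves its rows `NA` and is flagged, keeping the
#' report shape stable.
#'
#' @param tables list of wide modality tables for one sex, named
#'   `position, velocity, lp, mp, hp`.
#' @param control control genotype name.
#' @param comparisons character vector of comparison genotypes.
#' @param tmax time cutoff in seconds.
#' @return a `geotax_report` list: `table1`, `pvalues`, `lme`, `mwu_grids`,
#'   `peaks`, `gaps`.
#' @export
comparison_report <- function(tables, control, comparisons, tmax = Inf) {
  display <- c(position = "position", velocity = "velocity",
               lp = "low performer", mp = "middle performer",
               hp = "high performer")
  lmes <- list(); grids <- list(); peaks <- list()
  pvals <- list(); gaps <- character(0)
  for (mod in names(display)) {
    tab <- tables[[mod]]
    if (is.null(tab) || nrow(tab) == 0L) {
      gaps <- c(gaps, mod)
      next
    }
    lmes[[mod]] <- tryCatch({
      fit_lme(build_long_table(tab, control, comparisons, tmax))
    }, error = function(e) {
      warning(sprintf("LME failed for %s: %s", mod, conditionMessage(e)))
      NULL
    })
    for (g in comparisons) {
      lme_p <- if (!is.null(lmes[[mod]]))
        lmes[[mod]]$genotypes$hmp[lmes[[mod]]$genotypes$genotype == g]
      else NA_real_
      pk <- tryCatch(mwu_peaks(tab, control, g, tmax),
                     error = function(e) list(p = NA_real_))
      peaks[[paste(mod, g, sep = ".")]] <- pk
      grids[[paste(mod, g, sep = ".")]] <-
        tryCatch(mwu_timepoints(tab, control, g, tmax),
                 error = function(e) NULL)
      pvals[[g]][[paste0(display[mod], "_LME")]] <- lme_p
      pvals[[g]][[paste0(display[mod], "_Peak")]] <- pk$p
    }
  }
  metric_rows <- as.vector(t(outer(display, c("_LME", "_Peak"), paste0)))
  table1 <- data.frame(Metrics = metric_rows)
  for (g in comparisons) {
    table1[[paste(control, "vs", g)]] <- vapply(metric_rows, function(m) {
      p <- pvals[[g]][[m]] %||% NA_real_
      if (is.na(p)) NA_character_
      else sprintf("%.3f (%s)", p, star_annotation(p))
    }, character(1))
  }
  structure(list(table1 = table1, pvalues = pvals, lme = lmes,
                 mwu_grids = grids, peaks = peaks, gaps = gaps,
                 control = control, comparisons = comparisons,
                 tmax = tmax),
            class = "geotax_report")
}

#' @export
print.geotax_report <- function(x, ...) {
  cat(sprintf("Comparison report: control '%s' vs %s\n", x$control,
              paste(x$comparisons, collapse = ", ")))
  print(x$table1, row.names = FALSE)
  if (length(x$gaps))
    cat("Missing modalities:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}
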