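# Experiment-level aggregation ----------------------------------------------
#
# Joins per-recording summaries across an experiment into sex-split,
# replicate-labelled wide tables for five modalities: climbing position
# (cm), velocity (cm/s, the numerical gradient of position), and LP/MP/HP
# zone occupancy (%). Rows are replicate labels "Genotype_repN", columns
# are time points in seconds sorted numerically.

MODALITIES <- c("position", "velocity", "lp", "mp", "hp")

summary_files <- c(position = "total_position.csv", lp = "LP_pct.csv",
                   mp = "MP_pct.csv", hp = "HP_pct.csv")

#' Collect an experiment into the ten modality tables
#'
#' For every vial of every recording folder (folders are sorted
#' lexicographically for label stability) a replicate label
#' `<Genotype>_rep<N>` is assigned, where `N` counts prior occurrences of
#' that genotype *within the same sex across all folders*. Velocity is
#' derived per replicate from its position series. Missing series trigger a
#' warning and an absent row, not a failure; a folder missing a required
#' file is skipped with a warning.
#'
#' @param folders character vector of recording folders, each holding
#'   `geotaxis_metadata.csv` and the four summary CSVs (see
#'   [write_recording_outputs()]).
#' @return nested list `tables[[sex]][[modality]]` for sexes `"M", "F"` and
#'   modalities `position, velocity, lp, mp, hp`; each a wide data.frame
#'   with a `replicate` column then time columns.
#' @export
collect_experiment <- function(folders) {
  folders <- sort(folders)
  series <- list(M = list(), F = list())
  counts <- new.env(parent = emptyenv())
  for (folder in folders) {
    meta <- tryCatch(read_metadata(folder), error = function(e) NULL)
    tabs <- lapply(summary_files, function(f) {
      p <- file.path(folder, f)
      if (file.exists(p)) utils::read.csv(p, check.names = FALSE) else NULL
    })
    if (is.null(meta) || any(vapply(tabs, is.null, TRUE))) {
      warning(sprintf("folder '%s' is missing required files; skipped",
                      folder))
      next
    }
    for (i in seq_len(nrow(meta))) {
      sex <- meta$Gender[i]; geno <- meta$Genotype[i]
      vcol <- paste0("vial_", meta$Vial_Num[i])
      key <- paste(sex, geno, sep = "\r")
      n_prev <- if (!is.null(counts[[key]])) counts[[key]] else 0L
      counts[[key]] <- n_prev + 1L
      label <- sprintf("%s_rep%d", geno, n_prev + 1L)
      for (mod in names(summary_files)) {
        tab <- tabs[[mod]]
        if (!vcol %in% names(tab)) {
          warning(sprintf("vial %s absent from %s in '%s'; row skipped",
                          meta$Vial_Num[i], summary_files[mod], folder))
          next
        }
        vals <- tab[[vcol]]
        names(vals) <- as.character(tab$time_s)
        series[[sex]][[mod]][[label]] <- vals
      }
    }
  }
  out <- list(M = list(), F = list())
  for (sex in c("M", "F")) {
    for (mod in names(summary_files))
      out[[sex]][[mod]] <- series_to_wide(series[[sex]][[mod]])
    pos <- out[[sex]]$position
    out[[sex]]$velocity <- if (nrow(pos) > 0L && ncol(pos) > 2L)
      velocity_from_position(pos) else pos
    out[[sex]] <- out[[sex]][MODALITIES]
  }
  out
}

# Named list of (time -> value) vectors into a wide table on the union grid.
series_to_wide <- function(lst) {
  if (is.null(lst) || length(lst) == 0L)
    return(data.frame(replicate = character()))
  times <- sort(unique(as.numeric(unlist(lapply(lst, names)))))
  mat <- t(vapply(lst, function(v)
    as.numeric(v[as.character(times)]), numeric(length(times))))
  out <- data.frame(replicate = names(lst), mat, check.names = FALSE)
  names(out) <- c("replicate", as.character(times))
  rownames(out) <- NULL
  out
}

table_times <- function(table) as.numeric(names(table)[-1])

#' Velocity from a position table
#'
#' Numerical gradient of climbing height against the actual (possibly
#' non-uniform) time grid: central differences
#' `(y[i+1] - y[i-1]) / (t[i+1] - t[i-1])` at interior points, one-sided
#' differences at the two ends. Exact for linear series.
#'
#' @param position wide position table (`replicate` column + time columns).
#' @return wide velocity table on the same grid, cm/s.
#' @export
velocity_from_position <- function(position) {
  t <- table_times(position)
  if (length(t) < 2L) stop_geotax("need >= 2 time points for velocity")
  vel <- position
  for (r in seq_len(nrow(position))) {
    y <- as.numeric(position[r, -1])
    n <- length(y)
    g <- numeric(n)
    g[1] <- (y[2] - y[1]) / (t[2] - t[1])
    g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
    if (n > 2L) {
      i <- 2:(n - 1)
      g[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
    }
    vel[r, -1] <- g
  }
  vel
}

#' Per-genotype mean / SEM / N curves
#'
#' Replicates are grouped by the label prefix before `"_rep"`; per time
#' point the group mean, SEM and replicate count are computed (NA cells are
#' dropped per point).
#'
#' @param table a wide modality table.
#' @return data.frame `genotype, time_s, mean, sem, n`.
#' @export
genotype_curves <- function(table) {
  if (nrow(table) == 0L) stop_geotax("empty modality table")
  genos <- sub("_rep[0-9]+$", "", table$replicate)
  times <- table_times(table)
  rows <- list()
  for (g in unique(genos)) {
    sub <- as.matrix(table[genos == g, -1, drop = FALSE])
    rows[[g]] <- data.frame(
      genotype = g, time_s = times,
      mean = apply(sub, 2, function(v) mean(v, na.rm = TRUE)),
      sem = apply(sub, 2, function(v) sem(v)),
      n = apply(sub, 2, function(v) sum(!is.na(v))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the ten modality tables
#'
#' Sex-specific tables go to `Output Males` / `Output Females` directories
#' under `root`, one CSV per modality (`position.csv`, `velocity.csv`,
#' `lp.csv`, `mp.csv`, `hp.csv`), first column the replicate label.
#'
#' @param tables nested list from [collect_experiment()].
#' @param root experiment root directory.
#' @return invisibly, the written paths.
#' @export
write_modality_tables <- function(tables, root) {
  dirs <- c(M = file.path(root, "Output Males"),
            F = file.path(root, "Output Females"))
  paths <- character(0)
  for (sex in c("M", "F")) {
    dir.create(dirs[[sex]], recursive = TRUE, showWarnings = FALSE)
    for (mod in MODALITIES) {
      p <- file.path(dirs[[sex]], paste0(mod, ".csv"))
      utils::write.csv(tables[[sex]][[mod]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' @rdname write_modality_tables
#' @param path a single modality CSV path.
#' @export
read_modality_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1] != "replicate")
    stop_geotax("'%s' is not a modality table (no replicate column)", path)
  tab
}
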