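# Writes a minimal recording folder (metadata + the four summary CSVs)
# without running the tracker.
write_fake_folder <- function(root, name, vials, genotypes, genders,
                              times = c(0, 0.5, 1), offset = 0) {
  folder <- file.path(root, name)
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(Vial_Num = vials, Genotype = genotypes,
                              Gender = genders, N = 10),
                   file.path(folder, "geotaxis_metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  agg <- do.call(rbind, lapply(vials, function(v)
    data.frame(time_s = times, vial_num = v,
               mean_height_cm = offset + v + times,
               mean_height_sem = 0.1,
               pct_lp = 50, pct_lp_sem = 1, pct_mp = 30, pct_mp_sem = 1,
               pct_hp = 20, pct_hp_sem = 1, n_trims = 4L)))
  write_recording_outputs(agg, folder)
  folder
}

test_that("replicate labels count genotype occurrences across folders", {
  root <- withr::local_tempdir()
  folders <- vapply(1:3, function(k)
    write_fake_folder(root, sprintf("set%d", k), vials = 1:2,
                      genotypes = "w1118", genders = "M"), "")
  tabs <- collect_experiment(folders)
  expect_equal(tabs$M$position$replicate, paste0("w1118_rep", 1:6))
  expect_equal(nrow(tabs$F$position), 0)
  expect_equal(names(tabs$M), c("position", "velocity", "lp", "mp", "hp"))
  # values land in the right cells: vial 2 of set1 is w1118_rep2
  expect_equal(as.numeric(tabs$M$position[2, -1]), 2 + c(0, 0.5, 1))
})

test_that("a single-vial experiment yields single-row tables", {
  root <- withr::local_tempdir()
  f <- write_fake_folder(root, "only", vials = 5, genotypes = "mut",
                         genders = "F")
  tabs <- collect_experiment(f)
  expect_equal(nrow(tabs$F$position), 1)
  expect_equal(tabs$F$position$replicate, "mut_rep1")
})

test_that("missing files or series warn and skip instead of failing", {
  root <- withr::local_tempdir()
  f1 <- write_fake_folder(root, "good", vials = 1, genotypes = "g",
                          genders = "M")
  f2 <- file.path(root, "broken")
  dir.create(f2)
  utils::write.csv(data.frame(Vial_Num = 1, Genotype = "g", Gender = "M",
                              N = 10),
                   file.path(f2, "geotaxis_metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  expect_warning(tabs <- collect_experiment(c(f1, f2)), "missing required")
  expect_equal(nrow(tabs$M$position), 1)
  # metadata naming a vial absent from the summaries: warned, row absent
  f3 <- write_fake_folder(root, "partial", vials = 1, genotypes = "h",
                          genders = "M")
  meta <- utils::read.csv(file.path(f3, "geotaxis_metadata.csv"))
  meta$Vial_Num <- 9
  utils::write.csv(meta, file.path(f3, "geotaxis_metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  w <- capture_warnings(tabs3 <- collect_experiment(f3))
  expect_true(any(grepl("absent from", w)))
  expect_equal(nrow(tabs3$M$position), 0)
})

test_that("velocity is the numerical gradient against the time grid", {
  tab <- data.frame(replicate = c("a_rep1", "a_rep2"),
                    `0` = c(1, 0), `0.5` = c(1, 0.5), `1` = c(1, 1),
                    check.names = FALSE)
  vel <- velocity_from_position(tab)
  expect_equal(as.numeric(vel[1, -1]), c(0, 0, 0))   # constant position
  expect_equal(as.numeric(vel[2, -1]), c(1, 1, 1))   # linear position
  # quadratic position t^2 on {0, 0.5, 1}: central difference at 0.5 is 1
  quad <- data.frame(replicate = "q_rep1", `0` = 0, `0.5` = 0.25, `1` = 1,
                     check.names = FALSE)
  gv <- as.numeric(velocity_from_position(quad)[1, -1])
  expect_equal(gv[2], 1)
  expect_equal(gv[1], 0.5)  # one-sided at the left end
  expect_equal(gv[3], 1.5)  # one-sided at the right end
  expect_error(velocity_from_position(tab[, 1:2]), ">= 2 time points")
})

test_that("genotype curves report mean, SEM and replicate count", {
  tab <- data.frame(replicate = c("g_rep1", "g_rep2", "h_rep1"),
                    `0` = c(2, 4, 7), `1` = c(2, 4, 7),
                    check.names = FALSE)
  cur <- genotype_curves(tab)
  g <- cur[cur$genotype == "g", ]
  expect_equal(g$mean, c(3, 3))
  expect_equal(g$sem, c(1, 1)) # sd sqrt(2) / sqrt(2)
  expect_equal(g$n, c(2L, 2L))
  expect_equal(cur$n[cur$genotype == "h"], c(1L, 1L))
  expect_equal(cur$sem[cur$genotype == "h"], c(0, 0))
})

test_that("the ten modality tables round-trip through CSV", {
  root <- withr::local_tempdir()
  f <- write_fake_folder(root, "rt", vials = 1:2,
                         genotypes = c("a", "b"), genders = c("M", "F"))
  tabs <- collect_experiment(f)
  write_modality_tables(tabs, root)
  expect_true(dir.exists(file.path(root, "Output Males")))
  expect_true(dir.exists(file.path(root, "Output Females")))
  for (sex in c("M", "F")) {
    dir <- file.path(root, if (sex == "M") "Output Males"
                     else "Output Females")
    expect_length(list.files(dir, pattern = "\\.csv$"), 5)
    back <- read_modality_table(file.path(dir, "position.csv"))
    expect_equal(back, tabs[[sex]]$position)
  }
})
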