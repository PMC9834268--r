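test_that("screen table joins assignments and measurements one row per anchor-timepoint", {
  layout <- build_hexagonal_layout(154)
  cb <- default_codebook()
  sim <- simulate_screen(layout, cb, timepoints_h = c(0, 72), seed = 41,
                         optics = NULL)
  meas <- measurements_from_truth(sim$truth)
  asg <- assignments_from_truth(sim$truth)
  tab <- build_screen_table(asg, meas, cb)
  expect_s3_class(tab, "screen_table")
  expect_equal(nrow(tab), 154 * 2)
  expect_false(any(duplicated(tab[c("anchor_id", "timepoint_h")])))
  # per-condition row counts match the ground-truth allocation exactly
  expect_equal(as.vector(table(tab$condition_label)),
               as.vector(table(sim$truth$condition_label)))
  # dose is reported post-merge
  expect_equal(unique(tab$dose_umol[tab$condition_label == "tamoxifen_250"]),
               250 / cb$dilution_factor)
})

test_that("UNASSIGNED rows are carried but excluded, and exclusion is local", {
  layout <- build_hexagonal_layout(20, chamber_area_mm2 = 20, pitch_um = 800)
  cb <- default_codebook()
  sim <- simulate_screen(layout, cb, timepoints_h = 24, seed = 13,
                         optics = NULL)
  meas <- measurements_from_truth(sim$truth)
  asg <- assignments_from_truth(sim$truth)
  tab_full <- build_screen_table(asg, meas, cb)

  drop_id <- asg$anchor_id[1]
  drop_cond <- asg$condition_label[1]
  asg2 <- asg
  asg2$condition_label[1] <- NA
  tab_drop <- build_screen_table(asg2, meas, cb)
  expect_equal(nrow(tab_drop), nrow(tab_full))  # row carried
  expect_true(grepl("unassigned",
                    tab_drop$qc_flags[tab_drop$anchor_id == drop_id]))

  mean_by_cond <- function(tab) {
    ok <- tab$qc_flags == "" & !is.na(tab$condition_label)
    tapply(tab$viability[ok], tab$condition_label[ok], mean)
  }
  m1 <- mean_by_cond(tab_full)
  m2 <- mean_by_cond(tab_drop)
  other <- setdiff(names(m2), drop_cond)
  expect_equal(m1[other], m2[other])  # nothing else moved
})

test_that("duplicate keys are rejected", {
  layout <- build_hexagonal_layout(10, chamber_area_mm2 = 20, pitch_um = 800)
  cb <- default_codebook()
  sim <- simulate_screen(layout, cb, timepoints_h = 24, seed = 2,
                         optics = NULL)
  meas <- measurements_from_truth(sim$truth)
  asg <- assignments_from_truth(sim$truth)
  expect_error(build_screen_table(asg, rbind(meas, meas[1, ]), cb),
               "duplicate")
  expect_error(build_screen_table(rbind(asg, asg[1, ]), meas, cb),
               "duplicate")
})

test_that("dose-response summaries follow the Hill ground truth", {
  layout <- build_hexagonal_layout(154)
  cb <- default_codebook()
  sim <- simulate_screen(layout, cb, timepoints_h = 144, seed = 77,
                         optics = NULL)
  tab <- build_screen_table(assignments_from_truth(sim$truth),
                            measurements_from_truth(sim$truth), cb)
  dr <- dose_response_summary(tab, "tamoxifen")
  expect_equal(dr$dose_umol, sort(dr$dose_umol))
  # top dose kills far more than bottom dose
  expect_gt(dr$mean_dead_intensity_mean[nrow(dr)],
            dr$mean_dead_intensity_mean[1])
  expect_gt(dr$viability_mean[1], dr$viability_mean[nrow(dr)])

  # top-dose-only phenotype: only 250 umol/L exceeds the DMSO control
  ctrl <- tab[tab$drug == "dmso" & tab$qc_flags == "", ]
  lim <- mean(ctrl$mean_dead_intensity) + 2 * stats::sd(ctrl$mean_dead_intensity)
  expect_gt(dr$mean_dead_intensity_mean[nrow(dr)], lim)
  expect_true(all(dr$mean_dead_intensity_mean[-nrow(dr)] < lim))

  # a flat (alpelisib) arm stays within noise of the control
  dr0 <- dose_response_summary(tab, "alpelisib")
  expect_true(all(dr0$mean_dead_intensity_mean < lim))
  expect_error(dose_response_summary(tab, "bortezomib"), "unknown drug")
})

test_that("growth curves show the expected line phenotypes", {
  layout <- build_hexagonal_layout(60, chamber_area_mm2 = 60, pitch_um = 800)
  cb <- default_codebook(conditions = c("dmso_a", "dmso_b"))
  # fast-growing line with flat mortality
  sim <- simulate_screen(layout, cb, timepoints_h = c(0, 72, 144), seed = 3,
                         optics = NULL)
  tab <- build_screen_table(assignments_from_truth(sim$truth),
                            measurements_from_truth(sim$truth), cb)
  gc <- growth_curves(tab)
  a <- gc[gc$condition_label == "dmso_a", ]
  expect_true(all(diff(a$diameter_median) > 0))
  expect_true(all(abs(a$viability_median - a$viability_median[1]) < 0.05))

  # epithelial-like arm decaying at late timepoints (constructed series)
  truth2 <- sim$truth
  late <- truth2$timepoint_h == 144
  truth2$true_dead_fraction[late] <- truth2$true_dead_fraction[late] + 0.4
  tab2 <- build_screen_table(assignments_from_truth(truth2),
                             measurements_from_truth(truth2), cb)
  gc2 <- growth_curves(tab2)
  b <- gc2[gc2$condition_label == "dmso_a", ]
  expect_lt(b$viability_median[3], b$viability_median[2])

  expect_error(growth_curves(tab[tab$timepoint_h == 0, ]), "two timepoints")
})

test_that("a single-anchor group reproduces that anchor's values", {
  layout <- build_hexagonal_layout(10, chamber_area_mm2 = 20, pitch_um = 800)
  cb <- default_codebook()
  sim <- simulate_screen(layout, cb, timepoints_h = c(0, 48), seed = 19,
                         optics = NULL)
  tab <- build_screen_table(assignments_from_truth(sim$truth),
                            measurements_from_truth(sim$truth), cb)
  counts <- table(tab$condition_label[tab$timepoint_h == 0])
  solo <- names(counts)[counts == 1][1]
  expect_false(is.na(solo))  # seed 19 allocates several singletons
  gc <- growth_curves(tab)
  row0 <- tab[tab$condition_label == solo & tab$timepoint_h == 0, ]
  expect_equal(gc$diameter_median[gc$condition_label == solo &
                                    gc$timepoint_h == 0],
               row0$diameter_um)
})

test_that("two-way ANOVA matches the brute-force balanced oracle to 1e-10", {
  # 2 x 2 balanced toy table; textbook sums of squares computed explicitly
  set.seed(101)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:5)
  d$y <- stats::rnorm(nrow(d)) + (d$A == "a2") * 0.8 +
    (d$B == "b2") * (-0.5) + (d$A == "a2" & d$B == "b2") * 0.3

  grand <- mean(d$y)
  ybar_a <- tapply(d$y, d$A, mean)
  ybar_b <- tapply(d$y, d$B, mean)
  ybar_ab <- tapply(d$y, interaction(d$A, d$B), mean)
  n_cell <- 5
  ss_a <- 2 * n_cell * sum((ybar_a - grand)^2)
  ss_b <- 2 * n_cell * sum((ybar_b - grand)^2)
  ss_cells <- n_cell * sum((ybar_ab - grand)^2)
  ss_int <- ss_cells - ss_a - ss_b
  ss_res <- sum((d$y - ybar_ab[interaction(d$A, d$B)])^2)

  res <- two_way_anova(d, response = "y", factors = c("A", "B"),
                       use_qc = FALSE)
  expect_equal(res$sum_sq, c(ss_a, ss_b, ss_int, ss_res), tolerance = 1e-10)
  f_a <- (ss_a / 1) / (ss_res / 16)
  expect_equal(res$statistic[1], f_a, tolerance = 1e-10)
  expect_equal(res$p_value[1],
               stats::pf(f_a, 1, 16, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("two-way ANOVA agrees with the linear-model oracle on balanced designs", {
  set.seed(202)
  for (i in 1:5) {
    a <- sample(2:4, 1)
    b <- sample(2:3, 1)
    n <- sample(3:6, 1)
    d <- expand.grid(A = paste0("a", seq_len(a)), B = paste0("b", seq_len(b)),
                     rep = seq_len(n))
    d$y <- stats::rnorm(nrow(d), sd = 2) +
      as.numeric(d$A) * 0.5 + as.numeric(d$B) * runif(1)
    res <- two_way_anova(d, response = "y", factors = c("A", "B"),
                         use_qc = FALSE)
    oracle <- stats::anova(stats::lm(y ~ A * B, data = d))
    expect_equal(res$sum_sq, oracle$`Sum Sq`, tolerance = 1e-8)
    expect_equal(res$statistic[1:3], oracle$`F value`[1:3], tolerance = 1e-8)
    expect_equal(res$p_value[1:3], oracle$`Pr(>F)`[1:3], tolerance = 1e-8)
  }
})

test_that("ANOVA rejects degenerate designs with actionable errors", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- 1  # no variance at all
  expect_error(two_way_anova(d, "y", c("A", "B"), use_qc = FALSE),
               "degenerate")

  d2 <- d
  d2$y <- rnorm(nrow(d2))
  d2 <- d2[!(d2$A == "a2" & d2$B == "b2"), ]
  expect_error(two_way_anova(d2, "y", c("A", "B"), use_qc = FALSE),
               "empty design cell: A = a2, B = b2")

  d3 <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
  d3$y <- rnorm(4)
  expect_error(two_way_anova(d3, "y", c("A", "B"), use_qc = FALSE),
               "2 replicates")
})

test_that("co-culture ANOVA flags the immune effect", {
  imm <- simulate_coculture(immune_ratio = 10, timepoints_h = c(1, 24, 48),
                            seed = 55, n_anchors = 40)
  ctl <- simulate_coculture(immune_ratio = 0, timepoints_h = c(1, 24, 48),
                            seed = 56, n_anchors = 40)
  d <- rbind(
    data.frame(arm = "cd8", timepoint_h = imm$timepoint_h,
               viability = 1 - imm$true_dead_fraction),
    data.frame(arm = "control", timepoint_h = ctl$timepoint_h,
               viability = 1 - ctl$true_dead_fraction))
  res <- two_way_anova(d, response = "viability",
                       factors = c("arm", "timepoint_h"), use_qc = FALSE)
  expect_lt(res$p_value[res$term == "arm"], 0.001)
})

test_that("pairwise Holm annotation runs and orders p-values sensibly", {
  layout <- build_hexagonal_layout(154)
  cb <- default_codebook()
  sim <- simulate_screen(layout, cb, timepoints_h = 144, seed = 7,
                         optics = NULL)
  tab <- build_screen_table(assignments_from_truth(sim$truth),
                            measurements_from_truth(sim$truth), cb)
  pw <- pairwise_vs_control(tab, reference = "dmso_a")
  expect_true(all(pw$p_holm >= pw$p_value, na.rm = TRUE))
  top <- pw[pw$condition == "tamoxifen_250", ]
  expect_lt(top$p_holm, 0.01)
})
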