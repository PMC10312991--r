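# Synthetic generator: layouts, tabular screens, dose series, calibration.

test_that("dose ladder reproduces the standard 11-point two-fold series", {
  expect_equal(dose_ladder(0.04, 40, 11),
               c(0.04, 0.08, 0.16, 0.31, 0.63, 1.25, 2.5, 5, 10, 20, 40))
})

test_that("layouts fill plates deterministically and respect capacity", {
  # 384-well, 16+16 controls, 352 single-dose compounds -> fully assigned
  ca <- data.frame(compound_id = sprintf("c%03d", 1:352), dose_um = 10)
  lay <- make_layout(384, 16, ca)
  expect_equal(nrow(lay), 384)
  expect_equal(sum(lay$role == "compound"), 352)
  expect_equal(sum(lay$role == "negative_control"), 16)
  expect_equal(sum(lay$role == "positive_control"), 16)
  expect_equal(sum(lay$role == "empty"), 0)
  # 96-well, 8+8 controls, 10 compounds x 8 doses -> exactly 80 compound wells
  ca2 <- data.frame(compound_id = rep(sprintf("c%02d", 1:10), each = 8),
                    dose_um = rep(dose_ladder(0.31, 40, 8), 10))
  lay2 <- make_layout(96, 8, ca2)
  expect_equal(sum(lay2$role == "compound"), 80)
  # controls sit in the outermost two columns on each side
  cc <- lay2$col[lay2$role %in% c("negative_control", "positive_control")]
  expect_true(all(cc %in% c(1, 2, 11, 12)))
  # identical call -> identical layout
  expect_identical(make_layout(96, 8, ca2), lay2)
  # capacity errors
  expect_error(make_layout(96, 8, data.frame(compound_id = paste0("x", 1:90),
                                             dose_um = 1)),
               class = "tgn_capacity_error")
  expect_error(make_layout(96, 30, NULL), class = "tgn_capacity_error")
  # round trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_layout(lay2, path)
  back <- read_layout(path, 96)
  expect_equal(back$role, lay2$role)
  expect_equal(back$dose_um, lay2$dose_um)
})

test_that("effective ratio follows the planted 4PL and is monotone in dose", {
  pr <- genotype_preset("d", 1.8, 0.1, 0.02)
  eff <- compound_effect("c", efficacy = 1, ec50 = 5, hill = 2)
  d <- c(0.1, 0.5, 1, 2, 5, 10, 40)
  r <- effective_ratio(pr, eff, d)
  expect_true(all(diff(r) < 0))
  expect_equal(effective_ratio(pr, eff, 5), 1.8 - 0.5 * 0.8)  # half effect
  expect_equal(effective_ratio(pr, NULL, 10), 1.8)
  # efficacy bounded: saturating dose removes at most the gap to 1
  expect_gt(effective_ratio(pr, eff, 1e6), 1 - 1e-6)
})

test_that("well tables are deterministic and planted effects are encoded", {
  pr <- tgn_presets("fibroblast_primary")
  ca <- data.frame(compound_id = sprintf("c%02d", 1:20), dose_um = 10)
  lay <- make_layout(96, 8, ca)
  effects <- c(
    lapply(1:5, function(i) compound_effect(sprintf("c%02d", i),
                                            efficacy = 1, ec50 = 0.5)),
    lapply(6:20, function(i) compound_effect(sprintf("c%02d", i))))
  names(effects) <- sprintf("c%02d", 1:20)
  w1 <- simulate_well_table(lay, pr, effects, n_plates = 2, seed = 7)
  w2 <- simulate_well_table(lay, pr, effects, n_plates = 2, seed = 7)
  expect_identical(w1, w2)
  w3 <- simulate_well_table(lay, pr, effects, n_plates = 2, seed = 8)
  expect_false(identical(w1$measured_ratio, w3$measured_ratio))
  expect_true(all(w1$truth_class[w1$compound_id %in% sprintf("c%02d", 1:5)]
                  == "active"))
  expect_true(all(w1$truth_class[w1$compound_id %in% sprintf("c%02d", 6:20)]
                  == "inactive"))
  # missing effect -> configuration error
  expect_error(simulate_well_table(lay, pr, effects[-1]),
               class = "tgn_config_error")
})

test_that("toxic compound at tox_ec50 halves the expected cell count", {
  pr <- genotype_preset("d", 1.4, 0.1, 0.02, mean_cells_per_well = 400)
  eff <- compound_effect("t", tox_ec50 = 10)
  ca <- data.frame(compound_id = "t", dose_um = 10)
  lay <- make_layout(96, 8, ca)
  counts <- vapply(1:40, function(s) {
    w <- simulate_well_table(lay, list(negative = pr, positive = pr),
                             list(t = eff), seed = s)
    w$cell_count[w$role == "compound"]
  }, numeric(1))
  expect_equal(mean(counts), 200, tolerance = 0.05)
})

test_that("null screens produce false actives at ~ the -3 SD tail rate", {
  # all compounds inert: per-well false-active events at z <= -3. With the
  # control SD estimated from 16 same-plate wells the exact marginal null
  # tail is Student-t: P(t_15 <= -3/sqrt(1 + 1/16)) ~ 0.54% (the Gaussian
  # tail 0.13% is the known-SD limit). Events cluster by plate (shared SD
  # estimate), so the rate is bounded, not pinpointed.
  pr <- tgn_presets("fibroblast_primary")
  n_cpd <- 352
  ca <- data.frame(compound_id = sprintf("c%03d", seq_len(n_cpd)),
                   dose_um = 10)
  lay <- make_layout(384, 16, ca)
  effects <- lapply(ca$compound_id, compound_effect)
  names(effects) <- ca$compound_id
  w <- simulate_well_table(lay, pr, effects, n_plates = 24, seed = 11)
  z <- well_zscores(w)
  rate <- mean(z$z_ratio <= -3)
  expect_lt(rate, 0.015)        # not grossly inflated over the t tail
  expect_lt(mean(z$z_ratio >= 3), 0.015)  # symmetric on the other side
})

test_that("per-well control statistics reproduce the printed calibration", {
  # pooled per-well mean within 2 SE and pooled SD within 30% over >= 60
  # wells, for every published preset pair
  for (nm in names(tgn_presets())) {
    pr <- tgn_presets(nm)
    lay <- make_layout(384, 16, NULL)
    w <- simulate_well_table(lay, pr, n_plates = 5, seed = 123)  # 80 wells/role
    for (role in c("negative", "positive")) {
      p <- pr[[role]]
      x <- w$measured_ratio[w$role == paste0(role, "_control")]
      pooled_sd <- sqrt(p$well_sd^2 + p$plate_sd^2)
      se <- pooled_sd / sqrt(length(x))
      # plate offsets are shared across wells, so the SE of the mean is
      # dominated by the plate term: use its own scale
      se_plate <- sqrt(p$plate_sd^2 / 5 + p$well_sd^2 / length(x))
      expect_lt(abs(mean(x) - p$true_ratio), 2.5 * se_plate + 2 * se)
      expect_lt(abs(sd(x) - pooled_sd) / pooled_sd, 0.30)
    }
  }
})

test_that("dose series honor the curve, noiseless and null cases", {
  pr <- genotype_preset("d", 1.8, 0.1, 0.05)
  eff <- compound_effect("c", efficacy = 0.8, ec50 = 2, hill = 1.2)
  s0 <- simulate_dose_series(eff, pr, n_replicates = 2, seed = 1,
                             noise_sd = 0)
  expect_equal(s0$ratio,
               effective_ratio(pr, eff, s0$dose_um))
  null <- compound_effect("n", efficacy = 0)
  s1 <- simulate_dose_series(null, pr, n_replicates = 2, seed = 1,
                             noise_sd = 0)
  expect_true(all(s1$ratio == 1.8))
  # determinism
  s2 <- simulate_dose_series(eff, pr, seed = 9)
  s3 <- simulate_dose_series(eff, pr, seed = 9)
  expect_identical(s2, s3)
})

test_that("rendered fields are deterministic, with blank and unit cases", {
  pr <- genotype_preset("d", 1.0, 0.05, 0.02)
  r1 <- render_field(pr, 6, seed = 5)
  r2 <- render_field(pr, 6, seed = 5)
  expect_identical(r1$field$channels, r2$field$channels)
  expect_identical(r1$truth$cells, r2$truth$cells)
  # n_cells = 0 -> noise-only image, empty truth
  r0 <- render_field(pr, 0, seed = 1)
  expect_equal(nrow(r0$truth$cells), 0)
  expect_true(all(r0$truth$labels$cell == 0))
  # true_ratio 1 -> ground-truth per-cell ratios average 1
  rr <- render_field(pr, 12, seed = 2)
  expect_lt(abs(mean(rr$truth$cells$true_ratio) - 1),
            3 * pr$cell_sd / sqrt(12))
  # impossible placement -> placement error
  expect_error(render_field(pr, 100, image_shape = c(64, 64), seed = 1),
               class = "tgn_placement_error")
})

test_that("autofluorescent compounds inflate background and bias the ratio", {
  pr <- genotype_preset("d", 1.8, 0.1, 0.01)
  af <- compound_effect("a", autofluorescent = TRUE, af_slope = 5)
  ser <- simulate_dose_series(af, pr, n_replicates = 2, seed = 3)
  clean <- simulate_dose_series(compound_effect("n"), pr, n_replicates = 2,
                                seed = 3)
  top <- ser$dose_um == max(ser$dose_um)
  expect_gt(mean(ser$background[top]), mean(clean$background[top]) + 50)
  # additive offset in both compartments pulls the ratio toward 1
  expect_lt(mean(ser$ratio[top]), mean(clean$ratio[top]) - 0.2)
})
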