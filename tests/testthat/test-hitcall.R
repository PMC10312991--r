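# Z-score hit calling and cascade arithmetic.

test_that("z-scores use same-plate negative controls", {
  wells <- data.frame(
    plate = 1,
    role = c(rep("negative_control", 2), "compound", "compound"),
    compound_id = c(NA, NA, "a", "b"),
    well = c("A01", "B01", "A03", "A04"),
    measured_ratio = c(1.0, 1.2, 0.8, 1.1),
    cell_count = c(100, 120, 110, 50))
  z <- well_zscores(wells)
  # neg mean 1.1, sd sqrt(0.02); compound a at 0.8 -> about -2.12
  expect_equal(z$z_ratio[z$compound_id == "a"],
               (0.8 - 1.1) / sd(c(1.0, 1.2)))
  expect_equal(round(z$z_ratio[z$compound_id == "a"], 2), -2.12)
  # compound at the control mean scores 0
  expect_equal(z$z_ratio[z$compound_id == "b"], 0)
  # degenerate controls error
  wells2 <- wells; wells2$measured_ratio[1:2] <- 1
  expect_error(well_zscores(wells2), class = "tgn_degenerate_controls")
})

test_that("negative-control wells self-normalize to mean 0, SD 1", {
  pr <- tgn_presets("fibroblast_primary")
  lay <- make_layout(384, 16, NULL)
  w <- simulate_well_table(lay, pr, n_plates = 4, seed = 5)
  zs <- unlist(lapply(1:4, function(p) {
    neg <- w$measured_ratio[w$plate == p & w$role == "negative_control"]
    (neg - mean(neg)) / sd(neg)
  }))
  expect_lt(abs(mean(zs)), 0.05)
  expect_equal(sd(zs), 1, tolerance = 0.05)
})

test_that("classification follows the threshold table exactly", {
  z <- data.frame(compound_id = c("a", "b", "c", "d", "e"),
                  z_ratio = c(-4, -4, -3, -2.9, 0),
                  z_count = c(0, -2.5, -2, 0, -1))
  calls <- classify_compounds(z, exclusions = "e")
  got <- setNames(calls$classification, calls$compound_id)
  expect_equal(got[["a"]], "active")
  expect_equal(got[["b"]], "active_toxic")
  expect_equal(got[["c"]], "active_toxic")  # boundary z = -3 / -2 inclusive
  expect_equal(got[["d"]], "inactive")
  expect_equal(got[["e"]], "excluded_unquantifiable")
})

test_that("classification is invariant under plate-wide affine rescaling", {
  pr <- tgn_presets("fibroblast_primary")
  ca <- data.frame(compound_id = sprintf("c%03d", 1:100), dose_um = 10)
  lay <- make_layout(384, 16, ca)
  effects <- lapply(ca$compound_id, function(id)
    compound_effect(id, efficacy = as.numeric(substr(id, 4, 4) == "1"),
                    ec50 = 0.5))
  names(effects) <- ca$compound_id
  w <- simulate_well_table(lay, pr, effects, seed = 6)
  c1 <- classify_compounds(well_zscores(w))
  w2 <- w; w2$measured_ratio <- 100 * w2$measured_ratio - 17
  c2 <- classify_compounds(well_zscores(w2))
  expect_equal(c1$classification, c2$classification)
  expect_equal(c1$z_ratio, c2$z_ratio, tolerance = 1e-9)
})

test_that("planted screens are recovered: sensitivity and false positives", {
  pr <- tgn_presets("fibroblast_primary")
  n <- 352
  ids <- sprintf("c%03d", seq_len(n))
  ca <- data.frame(compound_id = ids, dose_um = 10)
  lay <- make_layout(384, 16, ca)
  n_act <- 20  # strong actives: efficacy 1 at dose >> ec50
  effects <- c(
    lapply(ids[1:n_act], function(id)
      compound_effect(id, efficacy = 1, ec50 = 0.5, hill = 2)),
    lapply(ids[(n_act + 1):n], compound_effect))
  names(effects) <- ids
  hits <- 0; fp <- 0; n_runs <- 8
  for (s in 1:n_runs) {
    w <- simulate_well_table(lay, pr, effects, seed = s)
    calls <- classify_compounds(well_zscores(w))
    act <- calls$compound_id[calls$classification %in%
                               c("active", "active_toxic")]
    hits <- hits + sum(ids[1:n_act] %in% act)
    fp <- fp + sum(!(act %in% ids[1:n_act]))
  }
  expect_gte(hits / (n_act * n_runs), 0.9)
  # false positives occur at ~ the estimated-SD null tail, Student-t with
  # 15 df: P(t_15 <= -3/sqrt(1 + 1/16)) ~ 0.54%; events cluster per plate
  # (shared control-SD estimate), so bound the rate loosely
  n_null <- (n - n_act) * n_runs
  expect_lt(fp / n_null, 0.02)
})

test_that("cascade arithmetic reproduces printed screen percentages", {
  # printed groups overlap (the 1,435 toxicity exclusions and the 503
  # actives share the 61 active+toxic compounds), so they are reported as
  # overlapping groups against the stated denominator 28,838
  stages <- list(
    cascade_stage("primary", 28838,
                  c(excluded_unquantifiable = 26, inactive = 26961,
                    toxic = 1435, active = 503, active_nontoxic = 442,
                    active_toxic = 61),
                  survivors = 503),
    cascade_stage("secondary", 503, c(dual_replicate_pass = 51),
                  survivors = 51),
    cascade_stage("triage", 51, c(artifact = 34, unavailable = 1),
                  survivors = 16))
  rep_ <- cascade_report(stages)
  pct <- function(st, gr) rep_$percent[rep_$stage == st & rep_$group == gr]
  expect_equal(pct("primary", "survivors"), 1.7)   # 503 / 28,838
  expect_equal(pct("primary", "toxic"), 5.0)       # 1,435 / 28,838
  expect_equal(pct("primary", "inactive"), 93.5)
  expect_equal(pct("primary", "active"), 1.7)
  expect_equal(pct("primary", "active_nontoxic"), 1.5)
  expect_equal(pct("primary", "active_toxic"), 0.2)
  expect_equal(pct("secondary", "dual_replicate_pass"), 10.1)  # 51 / 503
  expect_equal(rep_$count[rep_$stage == "triage" & rep_$group == "survivors"],
               16)                                  # 51 - 34 - 1
  # percentages are always re-derivable from the stored counts
  denom <- c(primary = 28838, secondary = 503, triage = 51)[rep_$stage]
  expect_equal(rep_$percent,
               round_half_up(100 * rep_$count / unname(denom), 1))
})

test_that("cascade consistency violations raise errors", {
  s1 <- cascade_stage("a", 100, c(active = 10), survivors = 10)
  s2 <- cascade_stage("b", 11, c(pass = 5), survivors = 5)
  expect_error(cascade_report(list(s1, s2)), class = "tgn_consistency_error")
  expect_error(cascade_stage("x", 5, c(active = 10), survivors = 1),
               class = "tgn_consistency_error")
})
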