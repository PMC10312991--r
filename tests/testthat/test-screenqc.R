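# QC statistics, replicate correlation, Mann-Whitney, AUC.

test_that("robust Z-prime matches the median/MAD formula", {
  # zero-MAD groups give exactly 1
  expect_equal(robust_z_prime(rep(2, 4), rep(1, 4)), 1)
  # hand-computed oracle
  pos <- c(1.3, 1.35, 1.4); neg <- c(1.0, 1.1, 1.2)
  hand <- 1 - 3 * (1.4826 * median(abs(pos - median(pos))) +
                     1.4826 * median(abs(neg - median(neg)))) /
    abs(median(pos) - median(neg))
  expect_equal(robust_z_prime(pos, neg), hand)
  # wide spread on a small shift -> fails the 0.3 gate
  set.seed(4)
  neg2 <- rnorm(24, 1, 0.5); pos2 <- neg2 + 0.3
  expect_lt(robust_z_prime(pos2, neg2), 0.3)
  expect_error(robust_z_prime(c(1, 1), c(1, 1)),
               class = "tgn_separation_error")
  # invariance under a joint affine transform
  a <- 3.2; b <- -1.4
  expect_equal(robust_z_prime(a * pos + b, a * neg + b),
               robust_z_prime(pos, neg))
})

test_that("SSMD matches its closed form and symmetry properties", {
  # printed primary-screen control stats clear the >= 3 gate
  expect_equal(ssmd_from_stats(1.34, 0.05, 1.10, 0.02),
               0.24 / sqrt(0.0029))
  expect_gte(ssmd_from_stats(1.34, 0.05, 1.10, 0.02), 3)
  x <- c(1.3, 1.4, 1.5); y <- c(1.0, 1.05, 1.1)
  expect_equal(ssmd(x, y), (mean(x) - mean(y)) / sqrt(var(x) + var(y)))
  expect_equal(ssmd(x, x), 0)
  expect_equal(ssmd(y, x), -ssmd(x, y))
  # shift invariance; positive joint scaling leaves magnitude unchanged
  expect_equal(ssmd(x + 5, y + 5), ssmd(x, y))
  expect_equal(ssmd(2 * x, 2 * y), ssmd(x, y))
})

test_that("inter-assay CV is the percent SD of per-plate means", {
  expect_equal(inter_assay_cv(c(1, 1, 1)), 0)
  expect_equal(inter_assay_cv(c(0.9, 1.0, 1.1)), 100 * 0.1 / 1.0)
  expect_equal(inter_assay_cv(3 * c(0.9, 1.0, 1.1)),
               inter_assay_cv(c(0.9, 1.0, 1.1)))
})

test_that("plate gating removes exactly the failing plates", {
  qc <- data.frame(plate = 1:3, z_prime_robust = c(0.5, 0.1, 0.6),
                   ssmd = c(5, 8, 4), cv_percent = 2,
                   n_pos = 16, n_neg = 16, pass = NA)
  g <- gate_plates(qc)
  expect_equal(g$failed, 2)
  expect_equal(g$passed, c(1, 3))
  qc$z_prime_robust[2] <- 0.5
  expect_equal(gate_plates(qc)$failed, numeric(0))
})

test_that("replicate correlation: perfect duplicates, null, ratio vs intensity", {
  pr <- tgn_presets("fibroblast_primary")
  lay <- make_layout(384, 16, data.frame(
    compound_id = sprintf("c%03d", 1:352), dose_um = 10))
  effects <- lapply(sprintf("c%03d", 1:352), function(id)
    compound_effect(id, efficacy = runif(1), ec50 = 10))
  names(effects) <- sprintf("c%03d", 1:352)
  set.seed(2)
  w <- simulate_well_table(lay, pr, effects, n_plates = 6, seed = 2)
  # duplicated plates with zero noise -> r = 1
  wdup <- w[w$plate %in% 1:2, ]
  wdup$measured_ratio[wdup$plate == 2] <-
    wdup$measured_ratio[wdup$plate == 1]
  expect_equal(replicate_correlation(wdup, n_resamples = 5, seed = 1)$mean_r, 1)
  # independent noise -> |mean r| < 0.1
  wnull <- w
  wnull$measured_ratio <- rnorm(nrow(w))
  expect_lt(abs(replicate_correlation(wnull, n_resamples = 50,
                                      seed = 3)$mean_r), 0.1)
  # the ratio cancels the shared plate staining factor, raw intensity not
  rr <- replicate_correlation(w, "measured_ratio", n_resamples = 50, seed = 4)
  ri <- replicate_correlation(w, "intensity_tgn", n_resamples = 50, seed = 4)
  expect_gt(rr$mean_r, ri$mean_r)
  expect_error(replicate_correlation(w[w$plate == 1, ]),
               class = "tgn_config_error")
})

test_that("Mann-Whitney U matches exhaustive pair counting and enumeration", {
  # orientation: U counts pos > neg pairs
  mw <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw$U, 9)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  # identical samples -> p ~ 1
  expect_gte(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.99)
  # brute-force oracles over random small samples, with and without ties
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    pos <- sample(1:6, n1, TRUE); neg <- sample(1:6, n2, TRUE)
    u_pairs <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    mw <- mann_whitney(pos, neg)
    expect_equal(mw$U, u_pairs)
    expect_equal(mw$method, "exact")
    # enumeration oracle: all assignments of the pooled values
    vals <- c(pos, neg)
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) {
      p <- vals[ix]; n <- vals[-ix]
      sum(outer(p, n, ">")) + 0.5 * sum(outer(p, n, "=="))
    })
    p_oracle <- mean(abs(us - n1 * n2 / 2) >= abs(u_pairs - n1 * n2 / 2) - 1e-9)
    expect_equal(mw$p_value, p_oracle)
  }
  # tie-free exact case agrees with the stats package oracle
  pos <- c(2.3, 3.1, 4.8, 5.2); neg <- c(1.1, 2.9, 3.0)
  expect_equal(mann_whitney(pos, neg)$p_value,
               wilcox.test(pos, neg, exact = TRUE)$p.value)
  # large-sample normal approximation tracks the stats oracle
  set.seed(8)
  a <- rnorm(40, 0.3); b <- rnorm(35)
  expect_equal(mann_whitney(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("control_separation reports groups and a small p for separated sets", {
  set.seed(1)
  neg <- rnorm(20, 1.34, 0.05); pos <- rnorm(20, 1.10, 0.02)
  cs <- control_separation(neg, pos)
  expect_lt(cs$p_value, 1e-4)
  expect_equal(cs$n_neg, 20)
  expect_equal(cs$mean_neg, mean(neg))
})

test_that("AUC equals brute-force pair counting and is rank invariant", {
  set.seed(3)
  scores <- rnorm(60); labels <- rep(c(TRUE, FALSE), 30)
  brute <- mean(outer(scores[labels], scores[!labels],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_rank(scores, labels), brute)
  expect_equal(auc_rank(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0)), 1)
  # monotone transforms leave the AUC unchanged
  expect_equal(auc_rank(exp(scores), labels), auc_rank(scores, labels))
})

test_that("logistic train/test AUC behaves on null and separated data", {
  set.seed(5)
  null_cells <- data.frame(ratio = rnorm(600), label = rep(0:1, 300))
  a0 <- separation_auc(null_cells, seed = 1)
  expect_lt(abs(a0$auc - 0.5), 0.07)
  sep_cells <- data.frame(ratio = c(rnorm(300, 12), rnorm(300, 0)),
                          label = rep(1:0, each = 300))
  expect_equal(separation_auc(sep_cells, seed = 1)$auc, 1)
  # monotone-model invariance: AUC of scores equals AUC of the raw ratio
  cells <- data.frame(ratio = c(rnorm(200, 1.34, 0.1), rnorm(200, 1.1, 0.1)),
                      label = rep(1:0, each = 200))
  sa <- separation_auc(cells, seed = 2)
  split <- with(list(), {set.seed(sa$seed_used); sample(nrow(cells)) <= 0.7 * nrow(cells)})
  te <- cells[!split, ]
  expect_equal(sa$auc, auc_rank(te$ratio, te$label))
})
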