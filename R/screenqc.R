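# Plate-level quality control and control-separation statistics.

#' Robust Z-prime factor
#'
#' `1 - 3*(1.4826*MAD_pos + 1.4826*MAD_neg) / |median_pos - median_neg|`:
#' the Z' factor with medians and consistency-scaled MADs substituted for
#' means and SDs.
#'
#' @param pos,neg per-well means of positive / negative control wells
#'   (>= 2 each).
#' @return robust Z' (<= 1).
#' @export
robust_z_prime <- function(pos, neg) {
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  md <- abs(stats::median(pos) - stats::median(neg))
  if (md == 0)
    stop_tgn("tgn_separation_error",
             "equal control medians: robust Z' undefined")
  1 - 3 * (mad_sd(pos) + mad_sd(neg)) / md
}

#' Strictly standardized mean difference
#'
#' `(mean(pos) - mean(neg)) / sqrt(sd(pos)^2 + sd(neg)^2)` with sample SDs
#' (no UMVUE correction).
#'
#' @param pos,neg per-well means (>= 2 each).
#' @return SSMD (sign follows `pos - neg`).
#' @export
ssmd <- function(pos, neg) {
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  s <- sqrt(stats::sd(pos)^2 + stats::sd(neg)^2)
  if (s == 0) {
    if (mean(pos) == mean(neg))
      stop_tgn("tgn_separation_error", "zero variance and equal means")
    return(sign(mean(pos) - mean(neg)) * Inf)
  }
  (mean(pos) - mean(neg)) / s
}

#' SSMD from summary statistics
#'
#' Evaluates the SSMD directly from group means and SDs, e.g. from a printed
#' control summary.
#'
#' @param mean_pos,sd_pos,mean_neg,sd_neg group summary statistics.
#' @return SSMD.
#' @examples
#' ssmd_from_stats(1.34, 0.05, 1.10, 0.02)  # ~4.46
#' @export
ssmd_from_stats <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  (mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2)
}

#' Inter-assay coefficient of variation
#'
#' 100 * SD / mean of per-plate control means.
#'
#' @param plate_means per-plate means of the reference (negative) control
#'   wells; >= 2 plates.
#' @return CV in percent.
#' @export
inter_assay_cv <- function(plate_means) {
  stopifnot(length(plate_means) >= 2)
  m <- mean(plate_means)
  if (m == 0) stop_tgn("tgn_separation_error", "zero mean: CV undefined")
  100 * stats::sd(plate_means) / abs(m)
}

#' Per-plate QC from a well-level table
#'
#' Computes robust Z', SSMD and control counts for every plate using
#' same-plate controls only, plus the screen-level inter-assay CV of
#' per-plate negative-control means (repeated on every row), and the
#' pass flag `z_prime_robust >= z_prime_min & ssmd >= ssmd_min &
#' cv_percent <= cv_max`.
#'
#' @param wells data.frame with columns `plate`, `role`, `measured_ratio`
#'   (e.g. from [simulate_well_table()] or image analysis).
#' @param z_prime_min,ssmd_min,cv_max QC gate thresholds.
#' @return data.frame of class `plate_qc`: plate, z_prime_robust, ssmd,
#'   cv_percent, n_pos, n_neg, pass.
#' @export
plate_qc <- function(wells, z_prime_min = 0.3, ssmd_min = 3, cv_max = 10) {
  plates <- sort(unique(wells$plate))
  neg_means <- vapply(plates, function(p) {
    mean(wells$measured_ratio[wells$plate == p &
                                wells$role == "negative_control"])
  }, numeric(1))
  cv <- if (length(plates) >= 2) inter_assay_cv(neg_means) else 0
  rows <- lapply(plates, function(p) {
    w <- wells[wells$plate == p, ]
    neg <- w$measured_ratio[w$role == "negative_control"]
    pos <- w$measured_ratio[w$role == "positive_control"]
    zp <- robust_z_prime(pos, neg)
    sm <- ssmd(neg, pos)  # oriented so disease - rescue separation is > 0
    data.frame(plate = p, z_prime_robust = zp, ssmd = abs(sm),
               cv_percent = cv, n_pos = length(pos), n_neg = length(neg),
               pass = zp >= z_prime_min & abs(sm) >= ssmd_min & cv <= cv_max)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("plate_qc", "data.frame")
  out
}

#' Gate plates on QC thresholds
#'
#' @param qc a `plate_qc` data.frame.
#' @param z_prime_min,ssmd_min,cv_max thresholds.
#' @return list: `passed` (plate ids), `failed` (plate ids), `report`
#'   (qc with re-evaluated pass flag).
#' @export
gate_plates <- function(qc, z_prime_min = 0.3, ssmd_min = 3, cv_max = 10) {
  pass <- qc$z_prime_robust >= z_prime_min & qc$ssmd >= ssmd_min &
    qc$cv_percent <= cv_max
  qc$pass <- pass
  list(passed = qc$plate[pass], failed = qc$plate[!pass], report = qc)
}

#' Replicate correlation by repeated random plate splits
#'
#' Plates are split at random into two halves; per-well-position means of the
#' two halves are paired by well coordinate, a Pearson r is computed, and
#' the mean and SD of r over `n_resamples` splits are returned.
#'
#' @param wells data.frame with columns `plate`, `well`, and the chosen
#'   metric column.
#' @param metric column name to correlate (e.g. `"measured_ratio"` or
#'   `"intensity_tgn"`).
#' @param n_resamples number of random splits (default 100).
#' @param seed integer seed.
#' @return list with `mean_r`, `sd_r`, `n_resamples`.
#' @export
replicate_correlation <- function(wells, metric = "measured_ratio",
                                  n_resamples = 100, seed = 0) {
  plates <- sort(unique(wells$plate))
  if (length(plates) < 2)
    stop_tgn("tgn_config_error", "replicate correlation needs >= 2 plates")
  n_use <- 2L * (length(plates) %/% 2L)
  if (n_use < length(plates))
    warning("odd number of plates; one plate left out of each split")
  wl <- sort(unique(wells$well))
  m <- matrix(NA_real_, length(wl), length(plates),
              dimnames = list(wl, plates))
  m[cbind(match(wells$well, wl), match(wells$plate, plates))] <-
    wells[[metric]]
  with_seed(seed, {
    rs <- vapply(seq_len(n_resamples), function(i) {
      sel <- sample(length(plates), n_use)
      h1 <- sel[seq_len(n_use / 2)]; h2 <- sel[(n_use / 2 + 1):n_use]
      x <- rowMeans(m[, h1, drop = FALSE], na.rm = TRUE)
      y <- rowMeans(m[, h2, drop = FALSE], na.rm = TRUE)
      ok <- is.finite(x) & is.finite(y)
      stats::cor(x[ok], y[ok])
    }, numeric(1))
    list(mean_r = mean(rs), sd_r = stats::sd(rs), n_resamples = n_resamples)
  })
}

#' Mann-Whitney U test (pos vs neg)
#'
#' U counts pairs with pos > neg (ties count 1/2). Two-sided p-value by
#' exhaustive enumeration of all group assignments when both groups have
#' <= `exact_max` observations, otherwise by the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param pos,neg numeric samples.
#' @param exact_max largest group size for exact enumeration (default 8).
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(pos, neg, exact_max = 8) {
  n1 <- length(pos); n2 <- length(neg)
  u_of <- function(pos_idx, r) sum(r[pos_idx]) - n1 * (n1 + 1) / 2
  r <- rank(c(pos, neg))
  u <- u_of(seq_len(n1), r)
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, u_of, r = r)
    center <- n1 * n2 / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-9)
    return(list(U = u, p_value = p, method = "exact"))
  }
  ties <- table(c(pos, neg))
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "normal"))
  z <- (u - n1 * n2 / 2 - sign(u - n1 * n2 / 2) * 0.5) / sqrt(sigma2)
  list(U = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Control-separation report
#'
#' Mann-Whitney U test of negative vs positive control per-well means plus
#' group summaries.
#'
#' @param neg,pos per-well means (>= 3 each).
#' @return list: U, p_value, mean_neg, sd_neg, mean_pos, sd_pos, n_neg,
#'   n_pos, method.
#' @export
control_separation <- function(neg, pos) {
  stopifnot(length(neg) >= 3, length(pos) >= 3)
  mw <- mann_whitney(pos, neg)
  c(mw, list(mean_neg = mean(neg), sd_neg = stats::sd(neg),
             mean_pos = mean(pos), sd_pos = stats::sd(pos),
             n_neg = length(neg), n_pos = length(pos)))
}

#' Rank AUC of scores against binary labels
#'
#' @param scores numeric predictions.
#' @param labels logical or 0/1 (1 = disease/negative-control class, i.e.
#'   the class expected to score high).
#' @return AUC in 0..1 (ties count 1/2); equals U/(n1*n2).
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train/test AUC of a logistic model on the cargo ratio
#'
#' Splits per-cell data 70/30, fits a logistic regression of the genotype
#' label on the cargo ratio on the training split, and reports the rank AUC
#' of the predicted scores on the test split.
#'
#' @param cells data.frame with columns `ratio` and `label` (logical/0-1;
#'   1 = disease class).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed for the split.
#' @param predictors extra predictor column names (default none: the ratio
#'   is the sole predictor).
#' @return list: auc, n_train, n_test, seed_used.
#' @export
separation_auc <- function(cells, train_frac = 0.7, seed = 0,
                           predictors = character()) {
  stopifnot(nrow(cells) >= 10)
  vars <- c("ratio", predictors)
  for (attempt in 0:9) {
    s <- child_seed(seed, attempt)
    split <- with_seed(s, sample(nrow(cells)) <= train_frac * nrow(cells))
    tr <- cells[split, ]; te <- cells[!split, ]
    if (length(unique(tr$label)) == 2 && length(unique(te$label)) == 2) {
      f <- stats::as.formula(paste("label ~", paste(vars, collapse = "+")))
      # perfect separation only saturates the fit; scores stay monotone in
      # the ratio, so the rank AUC is unaffected
      fit <- suppressWarnings(
        stats::glm(f, data = tr, family = stats::binomial()))
      scores <- stats::predict(fit, newdata = te, type = "link")
      return(list(auc = auc_rank(scores, te$label),
                  n_train = nrow(tr), n_test = nrow(te), seed_used = s))
    }
  }
  stop_tgn("tgn_config_error",
           "could not obtain a two-class train/test split in 10 attempts")
}
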