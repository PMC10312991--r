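# Multiparametric morphological profiling: standardized feature matrices,
# PCA, PC-feature correlations, driver selection, condition profiles.

#' Assemble a standardized profile matrix
#'
#' Rows are cells (or per-image aggregates), columns the 85 manifest
#' features. Columns are standardized to mean 0 / SD 1 over the full pooled
#' matrix; zero-variance columns are dropped and recorded.
#'
#' @param records data.frame containing the 85 manifest feature columns
#'   (e.g. from [measure_cells()]); invalid rows (any non-finite feature)
#'   are dropped.
#' @param labels data.frame (or vector) of condition labels, row-aligned
#'   with `records`.
#' @param manifest_version expected manifest version of the records.
#' @return object of class `profile_matrix`: list with `x` (standardized
#'   matrix), `labels`, `center`, `scale`, `dropped` (constant features).
#' @export
build_profile_matrix <- function(records, labels = NULL,
                                 manifest_version = FEATURE_MANIFEST_VERSION) {
  rv <- attr(records, "manifest_version")
  if (!is.null(rv) && !identical(rv, manifest_version))
    stop_tgn("tgn_version_error",
             "record manifest %s does not match expected %s",
             rv, manifest_version)
  feats <- feature_names()
  missing <- setdiff(feats, names(records))
  if (length(missing))
    stop_tgn("tgn_version_error", "records lack manifest features: %s",
             paste(utils::head(missing, 5), collapse = ", "))
  x <- as.matrix(records[, feats, drop = FALSE])
  keep_rows <- apply(is.finite(x), 1, all)
  x <- x[keep_rows, , drop = FALSE]
  if (!is.null(labels)) {
    labels <- if (is.data.frame(labels)) labels[keep_rows, , drop = FALSE]
              else labels[keep_rows]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[scl == 0 | !is.finite(scl)]
  keep <- setdiff(colnames(x), dropped)
  xs <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  structure(list(x = xs, labels = labels, center = ctr[keep],
                 scale = scl[keep], dropped = dropped,
                 manifest_version = manifest_version),
            class = "profile_matrix")
}

#' Aggregate cell records per image/field before profiling
#'
#' @param records cell records with feature columns.
#' @param image_id vector identifying the image of each row.
#' @return data.frame of per-image feature means (one row per image) with
#'   column `image_id`; manifest version carried over.
#' @export
aggregate_by_image <- function(records, image_id) {
  feats <- feature_names()
  sp <- split(records[, feats, drop = FALSE], image_id)
  out <- do.call(rbind, lapply(sp, colMeans))
  out <- data.frame(image_id = names(sp), out, stringsAsFactors = FALSE)
  attr(out, "manifest_version") <- attr(records, "manifest_version") %||%
    FEATURE_MANIFEST_VERSION
  out
}

#' PCA of a profile matrix
#'
#' Singular value decomposition of the standardized matrix. Sign convention:
#' each component is oriented so that its largest-|loading| feature has a
#' positive loading.
#'
#' @param pm a `profile_matrix`.
#' @param k number of components (truncated to the matrix rank, with a
#'   warning).
#' @return list of class `pca_result`: `loadings` (features x k), `scores`
#'   (rows x k), `variance_explained` (length k fractions).
#' @export
run_pca <- function(pm, k = 2) {
  x <- pm$x
  stopifnot(k >= 1, nrow(x) >= 2)
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  rank_ <- sum(pr$sdev > pr$sdev[1] * 1e-10)
  if (k > rank_) {
    warning("k exceeds matrix rank; truncated to ", rank_)
    k <- rank_
  }
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(loadings = load, scores = scores,
                 variance_explained = ve[seq_len(k)]),
            class = "pca_result")
}

#' Correlate features with a principal component and select drivers
#'
#' Pearson r between every (standardized) feature column and the chosen PC
#' scores; driver features are those with `r > threshold` (signed, the
#' default) or `|r| > threshold` when `absolute = TRUE`.
#'
#' @param pm a `profile_matrix`.
#' @param pca matching `pca_result`.
#' @param component PC index (default 1).
#' @param threshold driver cutoff (default 0.75).
#' @param absolute select on |r| instead of signed r.
#' @return data.frame: feature, r, driver (logical), sorted by decreasing r.
#' @export
pc_feature_correlation <- function(pm, pca, component = 1, threshold = 0.75,
                                   absolute = FALSE) {
  stopifnot(component <= ncol(pca$scores),
            nrow(pca$scores) == nrow(pm$x))
  s <- pca$scores[, component]
  r <- as.vector(stats::cor(pm$x, s))
  drv <- if (absolute) abs(r) > threshold else r > threshold
  out <- data.frame(feature = colnames(pm$x), r = r, driver = drv,
                    stringsAsFactors = FALSE)
  out[order(-out$r), ]
}

#' Per-condition feature profiles
#'
#' Median standardized value of each (selected) feature per condition, as a
#' tidy table suitable for heatmap rendering.
#'
#' @param pm a `profile_matrix` whose `labels` give the condition of every
#'   row (vector or data.frame column `condition`).
#' @param features feature subset (default: all retained features).
#' @return data.frame: condition, feature, median_z.
#' @export
condition_profiles <- function(pm, features = colnames(pm$x)) {
  lab <- pm$labels
  if (is.data.frame(lab)) lab <- lab$condition
  if (is.null(lab)) stop_tgn("tgn_config_error", "profile matrix has no labels")
  stopifnot(all(features %in% colnames(pm$x)))
  conds <- unique(lab)
  rows <- lapply(conds, function(cd) {
    sub <- pm$x[lab == cd, features, drop = FALSE]
    data.frame(condition = cd, feature = features,
               median_z = apply(sub, 2, stats::median),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
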