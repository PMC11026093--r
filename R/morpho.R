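#' Mean anatomical feature over a subject's classed peaks
#'
#' Arithmetic mean of a per-vertex feature over the subject's peaks of one
#' class; missing feature values are excluded. An empty peak set yields `NA`
#' (the subject is dropped for that feature).
#'
#' @param peaks integer vector of peak vertices.
#' @param feature a [scalar_map()].
#' @return real scalar, or `NA` for an empty peak set.
#' @export
subject_feature_mean <- function(peaks, feature) {
  v <- as.integer(peaks)
  if (length(v) == 0L) return(NA_real_)
  mean(map_values(feature)[v], na.rm = TRUE)
}

#' Compare shared vs unique subject-level feature means
#'
#' Two-sample pooled-variance t-test between the per-subject means of the two
#' peak classes, reported with group means and SDs. The unit of analysis is
#' one value per subject (per hemisphere) per class, which avoids
#' pseudo-replication over peaks.
#'
#' @param means_shared,means_unique numeric vectors of per-subject means
#'   (NAs dropped).
#' @param feature_name tag for the output row.
#' @param welch use Welch's unequal-variance t instead of the pooled t
#'   (default FALSE; the gene comparisons use Welch).
#' @return one-row tibble of class `feature_comparison`: `feature`, `n_shared`,
#'   `n_unique`, `mean_shared`, `sd_shared`, `mean_unique`, `sd_unique`,
#'   `t_value`, `p_value`.
#' @export
compare_classes <- function(means_shared, means_unique,
                            feature_name = "feature", welch = FALSE) {
  xs <- means_shared[!is.na(means_shared)]
  ys <- means_unique[!is.na(means_unique)]
  if (length(xs) < 2L || length(ys) < 2L) {
    stop("each class needs at least two subject-level means")
  }
  ht <- if (welch) welch_t(xs, ys) else two_sample_t(xs, ys)
  out <- tibble::tibble(
    feature = feature_name,
    n_shared = length(xs), n_unique = length(ys),
    mean_shared = mean(xs), sd_shared = sd(xs),
    mean_unique = mean(ys), sd_unique = sd(ys),
    t_value = ht$t, p_value = ht$p
  )
  class(out) <- c("feature_comparison", class(out))
  out
}

#' Per-subject anatomical comparison table for shared vs unique peaks
#'
#' For every subject, peaks are classed by the group-wise shared/unique
#' clusters ([individual_class_peaks()]); each feature is then averaged per
#' subject per class and the two classes are compared with the pooled t-test.
#' P-values are FDR-corrected across features. The sulc feature is compared
#' on its absolute value (depth magnitude), matching the convention that peak
#' height is reported as a positive quantity.
#'
#' @param peaksets list of [peak_set()] objects, one per subject.
#' @param features named list of [scalar_map()] features (e.g. `sulc`,
#'   `curv`, `thickness`, `myelin`, `area`).
#' @param shared,unique `peak_clusters` tibbles of the two classes.
#' @return `feature_comparison` tibble, one row per feature, with `p_fdr`.
#' @export
morpho_feature_table <- function(peaksets, features, shared, unique) {
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    stop("`features` must be a named list")
  }
  per_subject <- purrr::map(peaksets, function(ps) {
    cls <- individual_class_peaks(ps, shared, unique)
    list(shared = cls$vertex[cls$class == "shared"],
         unique = cls$vertex[cls$class == "unique"])
  })
  rows <- purrr::imap(features, function(fmap, fname) {
    vals <- fmap
    if (fname == "sulc") vals <- scalar_map(abs(map_values(fmap)), name = "sulc")
    ms <- vapply(per_subject, function(p) subject_feature_mean(p$shared, vals), 0)
    mu <- vapply(per_subject, function(p) subject_feature_mean(p$unique, vals), 0)
    compare_classes(ms, mu, feature_name = fname)
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_bh(out$p_value)
  class(out) <- c("feature_comparison", class(tibble::tibble()))
  out
}
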