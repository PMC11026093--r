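#' Detect individual gyral peaks from a sulc map
#'
#' A vertex is a gyral peak iff its sulc value is strictly lower than the sulc
#' of every vertex in its k-ring neighborhood (lower sulc = higher on the
#' gyrus), and it lies in the gyral part of the sulc distribution, i.e. below
#' the `gyral_quantile` quantile of sulc over the hemisphere. Candidates with
#' a missing sulc value anywhere inside their ring are skipped with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param sulc a [scalar_map()] aligned to `mesh`.
#' @param k ring size (default 4, the human-template setting; use 3 for
#'   macaque-like templates).
#' @param gyral_quantile fraction in (0, 1]; a peak must have sulc below this
#'   quantile of the hemisphere's sulc distribution. Default 0.5 (median
#'   split: the gyral half).
#' @param subject_id,species metadata stored on the result.
#' @return integer vector of class `peak_set`: strictly increasing peak vertex
#'   indices, with attributes `subject_id` and `species`.
#' @export
detect_peaks <- function(mesh, sulc, k = 4, gyral_quantile = 0.5,
                         subject_id = "subject", species = "synthetic") {
  stopifnot_mesh(mesh)
  check_aligned(sulc, mesh, "sulc")
  if (k < 1L) stop("`k` must be >= 1")
  if (gyral_quantile <= 0 || gyral_quantile > 1) {
    stop("`gyral_quantile` must be in (0, 1]")
  }
  s <- map_values(sulc)
  rings <- k_ring_matrix(mesh, k)
  ring_min <- ring_reduce_min(rings, s)
  n_missing_ring <- ring_reduce_min(rings, as.numeric(!is.na(s)))
  thr <- quantile(s, gyral_quantile, na.rm = TRUE, names = FALSE)
  ok_ring <- n_missing_ring > 0          # no NA anywhere in the ring
  candidate <- !is.na(s) & s <= thr
  skipped <- candidate & !ok_ring
  if (any(skipped)) {
    warning(sum(skipped), " candidate vertices skipped: missing sulc in ring")
  }
  is_peak <- candidate & ok_ring & (s < ring_min)
  peaks <- which(is_peak)
  peak_set(peaks, subject_id = subject_id, species = species,
           n_vertices = n_vertices(mesh))
}

# column-wise min of values[u] over the sparse ring pattern (column v = ring
# of v); NA propagates (min with na.rm = FALSE semantics). Ring entries are
# contiguous in the CsparseMatrix slots, so each column is one segment.
ring_reduce_min <- function(rings, values) {
  vals <- values[rings@i + 1L]
  p <- rings@p
  vapply(seq_len(ncol(rings)), function(v) {
    if (p[v + 1L] == p[v]) return(Inf)
    suppressWarnings(min(vals[(p[v] + 1L):p[v + 1L]]))
  }, 0)
}

#' Peak set constructor
#'
#' @param peaks integer vector of peak vertex indices (1-based).
#' @param subject_id,species metadata.
#' @param n_vertices template vertex count used for validation.
#' @return sorted integer vector of class `peak_set`.
#' @export
peak_set <- function(peaks, subject_id = "subject", species = "synthetic",
                     n_vertices = NULL) {
  peaks <- sort(unique(as.integer(peaks)))
  if (length(peaks) > 0L && (anyNA(peaks) || peaks[1] < 1L)) {
    stop("peak indices must be positive integers")
  }
  if (!is.null(n_vertices) && length(peaks) > 0L &&
        peaks[length(peaks)] > n_vertices) {
    stop("peak index out of range for subject ", subject_id)
  }
  structure(peaks, subject_id = subject_id, species = species,
            class = c("peak_set", "integer"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set [", attr(x, "species"), "/", attr(x, "subject_id"), "]: ",
      length(x), " peaks\n", sep = "")
  invisible(x)
}

#' Accumulate subject peak sets into a group count map
#'
#' `count[v]` = number of subjects whose peak set contains template vertex v.
#' All peak sets must live on the same template (vertex-to-vertex
#' correspondence across subjects is assumed).
#'
#' @param peaksets list of [peak_set()] objects (or plain integer vectors).
#' @param n_vertices template vertex count.
#' @return a [scalar_map()] named `"count"` with attribute `n_subjects`.
#' @export
accumulate_count <- function(peaksets, n_vertices) {
  counts <- numeric(n_vertices)
  for (i in seq_along(peaksets)) {
    p <- as.integer(peaksets[[i]])
    if (length(p) > 0L && (min(p) < 1L || max(p) > n_vertices)) {
      sid <- attr(peaksets[[i]], "subject_id")
      stop("peak index out of range for subject ",
           if (is.null(sid)) i else sid)
    }
    counts[p] <- counts[p] + 1
  }
  scalar_map(counts, name = "count", n_subjects = length(peaksets))
}
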