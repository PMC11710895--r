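# Sliding-window correlation (SWC) dynamic connectivity.
#
# For each subject the pipeline slides a window of W TRs (default 61, shift
# 1 TR) along the T' x N ROI time series, computes the weighted Pearson
# correlation of all region pairs inside the window, zeroes the diagonal,
# and keeps the top `density` fraction (default 10%) of the strongest
# connections per window -- yielding the N x N x T dynamic connectivity
# tensor with T = floor((T' - W)/shift) + 1 (= T' - W + 1 at shift 1).

#' Sliding-window specification
#'
#' @param length_trs Window length W in TRs (default 61).
#' @param shift_trs Window shift in TRs (default 1, the highest temporal
#'   resolution).
#' @param shape `"rectangular"` (uniform weights, the default) or
#'   `"tapered"` (Tukey taper with parameter `taper_alpha`).
#' @param taper_alpha Tukey taper parameter in `[0, 1]`; 0 reduces to the
#'   rectangular window. Required when `shape = "tapered"`.
#' @param f_min Lowest frequency retained by the band-pass preprocessing, in
#'   Hz (default 0.008). Windows shorter than `1/f_min` seconds can show
#'   spurious connectivity fluctuations; [build_dynamic_networks()] warns
#'   when the window violates this guard.
#'
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_trs = 61L, shift_trs = 1L,
                        shape = c("rectangular", "tapered"),
                        taper_alpha = NULL, f_min = 0.008) {
  shape <- match.arg(shape)
  length_trs <- as.integer(length_trs)
  shift_trs <- as.integer(shift_trs)
  if (length_trs < 2L) {
    dc_stop("window length must be >= 2 TRs", "dynconn_size_error")
  }
  if (shift_trs < 1L) {
    dc_stop("window shift must be >= 1 TR", "dynconn_validation_error")
  }
  if (shape == "tapered") {
    if (is.null(taper_alpha) || !is.numeric(taper_alpha) ||
        taper_alpha < 0 || taper_alpha > 1) {
      dc_stop("tapered windows need taper_alpha in [0, 1]",
              "dynconn_validation_error")
    }
  }
  structure(list(length_trs = length_trs, shift_trs = shift_trs,
                 shape = shape, taper_alpha = taper_alpha, f_min = f_min),
            class = "window_spec")
}

#' Window weight vector
#'
#' Rectangular windows give uniform weights `1/W`; tapered windows use a
#' Tukey (cosine-tapered) profile with parameter `alpha` — the fraction of
#' the window inside the cosine lobes — renormalized to sum to 1. `alpha =
#' 0` is exactly rectangular.
#'
#' @param spec A [window_spec()].
#' @return Numeric vector of `W` non-negative weights summing to 1.
#' @export
make_window_weights <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  W <- spec$length_trs
  if (spec$shape == "rectangular" ||
      (spec$shape == "tapered" && spec$taper_alpha == 0)) {
    return(rep(1 / W, W))
  }
  a <- spec$taper_alpha
  n <- seq_len(W) - 1L
  w <- rep(1, W)
  edge <- a * (W - 1) / 2
  lo <- n < edge
  hi <- n > (W - 1) * (1 - a / 2)
  w[lo] <- 0.5 * (1 + cos(pi * (2 * n[lo] / (a * (W - 1)) - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * n[hi] / (a * (W - 1)) - 2 / a + 1)))
  w / sum(w)
}

#' Weighted Pearson correlation of a window segment
#'
#' With weights `w` summing to 1, weighted means `m_j = sum_t w_t x_tj`,
#' weighted covariance `cov_jk = sum_t w_t (x_tj - m_j)(x_tk - m_k)`, and
#' `r_jk = cov_jk / sqrt(cov_jj cov_kk)`. Uniform weights reproduce the
#' plain Pearson correlation of the segment.
#'
#' @param segment W x N numeric matrix (window rows, region columns).
#' @param weights W non-negative weights summing to 1.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
weighted_window_correlation <- function(segment, weights) {
  if (!is.matrix(segment) || nrow(segment) != length(weights)) {
    dc_stop("segment rows must match the weight vector length",
            "dynconn_dimension_error")
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    dc_stop("weights must be non-negative and sum to 1",
            "dynconn_validation_error")
  }
  m <- colSums(weights * segment)
  xc <- sweep(segment, 2L, m, "-")
  cv <- crossprod(xc * weights, xc)
  v <- diag(cv)
  tolv <- max(v) * 1e-14
  if (any(v <= tolv)) {
    dc_stop(sprintf("zero weighted variance in region %d within the window",
                    which(v <= tolv)[1L]), "dynconn_degenerate_signal_error")
  }
  r <- cv / sqrt(outer(v, v))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Proportional edge thresholding
#'
#' Zeroes the diagonal and keeps the `K = round(density * N(N-1)/2)`
#' (half-away-from-zero) strongest upper-triangle entries of a symmetric
#' matrix, mirroring to keep symmetry; all other entries are set to zero.
#' "Strongest" ranks by signed value by default (`rank_by = "signed"`), with
#' ties broken by ascending (row, column) index. Retained edges keep their
#' weights unless `binarize = TRUE`.
#'
#' @param mat N x N symmetric numeric matrix.
#' @param density Fraction of undirected edges to keep, in (0, 1].
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @param binarize Replace retained weights by 1 (default FALSE).
#' @return N x N symmetric matrix with zero diagonal and exactly `K`
#'   non-structural retained entries per triangle.
#' @export
proportional_threshold <- function(mat, density,
                                   rank_by = c("signed", "absolute"),
                                   binarize = FALSE) {
  rank_by <- match.arg(rank_by)
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1) {
    dc_stop("density must lie in (0, 1]", "dynconn_range_error")
  }
  check_symmetric(mat, tol = 1e-8, what = "connectivity matrix")
  n <- nrow(mat)
  pairs <- upper_tri_pairs(n)
  vals <- mat[cbind(pairs$i, pairs$j)]
  E <- n_undirected_edges(n)
  K <- as.integer(round_half_up(density * E))
  key <- if (rank_by == "signed") vals else abs(vals)
  keep_idx <- order(-key, pairs$i, pairs$j)[seq_len(K)]
  out <- matrix(0, n, n)
  wi <- pairs$i[keep_idx]
  wj <- pairs$j[keep_idx]
  wv <- if (binarize) rep(1, K) else vals[keep_idx]
  out[cbind(wi, wj)] <- wv
  out[cbind(wj, wi)] <- wv
  out
}

#' Build a subject's dynamic connectivity tensor
#'
#' Applies [weighted_window_correlation()] at window starts `1, 1+shift,
#' ...`, zeroes each slice's diagonal, and applies
#' [proportional_threshold()] per slice.
#'
#' @param ts A [subject_timeseries()].
#' @param spec A [window_spec()] (default: rectangular, W = 61, shift 1).
#' @param density Proportional threshold density (default 0.10).
#' @param rank_by,binarize Passed to [proportional_threshold()].
#' @param check_f_min Warn when `W * tr_seconds < 1/f_min` (default TRUE);
#'   set FALSE to suppress the guard.
#' @return An object of class `dynamic_connectivity_tensor`: list with
#'   `subject_id`, `data` (N x N x T array), `density`, `window`.
#' @export
build_dynamic_networks <- function(ts, spec = window_spec(), density = 0.10,
                                   rank_by = c("signed", "absolute"),
                                   binarize = FALSE, check_f_min = TRUE) {
  stopifnot(inherits(ts, "subject_timeseries"), inherits(spec, "window_spec"))
  rank_by <- match.arg(rank_by)
  Tp <- nrow(ts$data)
  N <- ncol(ts$data)
  W <- spec$length_trs
  if (Tp < W) {
    dc_stop(sprintf("time series length %d is shorter than the window (%d TRs)",
                    Tp, W), "dynconn_insufficient_length_error")
  }
  if (check_f_min && !is.null(spec$f_min) &&
      W * ts$tr_seconds < 1 / spec$f_min) {
    warning(sprintf(
      "window of %d TRs x %gs = %gs is shorter than 1/f_min = %gs; sliding-window correlations may show spurious fluctuations",
      W, ts$tr_seconds, W * ts$tr_seconds, 1 / spec$f_min))
  }
  weights <- make_window_weights(spec)
  starts <- seq.int(1L, Tp - W + 1L, by = spec$shift_trs)
  Tn <- length(starts)
  arr <- array(0, dim = c(N, N, Tn))
  for (k in seq_along(starts)) {
    seg <- ts$data[starts[k]:(starts[k] + W - 1L), , drop = FALSE]
    r <- weighted_window_correlation(seg, weights)
    diag(r) <- 0
    arr[, , k] <- proportional_threshold(r, density, rank_by = rank_by,
                                         binarize = binarize)
  }
  structure(
    list(subject_id = ts$subject_id, data = arr, density = density,
         window = spec, rank_by = rank_by, binarize = binarize),
    class = "dynamic_connectivity_tensor"
  )
}

#' @export
print.dynamic_connectivity_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_connectivity_tensor> %s: %d x %d regions x %d windows (W=%d, shift=%d, density=%.2f)\n",
    x$subject_id, d[1], d[2], d[3], x$window$length_trs,
    x$window$shift_trs, x$density))
  invisible(x)
}

#' Build dynamic networks for a whole cohort
#'
#' Convenience wrapper applying [build_dynamic_networks()] to every subject
#' of a [generate_cohort()] output or a named list of
#' [subject_timeseries()].
#'
#' @param x A `synthetic_cohort` or named list of `subject_timeseries`.
#' @param ... Passed to [build_dynamic_networks()].
#' @return Named list of `dynamic_connectivity_tensor` objects.
#' @export
build_cohort_networks <- function(x, ...) {
  ts_list <- if (inherits(x, "synthetic_cohort")) x$timeseries else x
  lapply(ts_list, build_dynamic_networks, ...)
}
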