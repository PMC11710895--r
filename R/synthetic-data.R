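# Synthetic cohort generator.
#
# Emulates post-preprocessing ROI signals: band-limited (0.009-0.08 Hz at
# TR = 2 s) BOLD-like series with a planted, group-dependent *dynamic*
# connectivity structure. Each of `n_components` spatial patterns is a set
# of co-activating regions (disjoint supports, non-negative loadings, unit
# norm); every subject expresses each pattern through a shared band-limited
# latent signal whose amplitude envelope is constant in the low-improvement
# group and slowly modulated (raised-sinusoid envelope, scaled by
# `effect_size`) in the high-improvement group. Behavioral change scores
# are drawn group-conditionally with the field's sign conventions: the
# high-improvement group sits less (negative sitting-time change) and walks
# more (positive step-count change). At `effect_size = 0` the two groups
# are exchangeable by construction.

#' Synthetic cohort configuration
#'
#' @param n_subjects Even number of subjects (default 36).
#' @param n_regions Number of regions (default 268; smaller values make
#'   desk-scale cohorts).
#' @param n_timepoints Time points per subject (default 197).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param band_hz Passband `(low, high)` in Hz (default `c(0.009, 0.08)`,
#'   the standard resting-state band).
#' @param n_components Number of planted spatial patterns (default 4);
#'   pattern k carries relative amplitude `1/sqrt(k)`.
#' @param effect_size Group difference in the time-varying component
#'   expression, in units of the constant (low-group) amplitude
#'   (default 2); 0 makes the groups exchangeable.
#' @param noise_sd Standard deviation of the band-limited background noise
#'   (default 1).
#' @param behavior_gap Separation of the group change-score means in units
#'   of the within-group SD (default 4; the median split then misassigns
#'   < 1% of subjects).
#' @param behavior_sd Within-group change-score SDs, named `st` (min/day)
#'   and `ns` (steps/day).
#' @param effect_mode `"dynamic"` (default: the group difference is a
#'   time-varying envelope) or `"static"` (the same mean amplitude
#'   difference held constant in time, for ablation).
#' @param seed Integer seed; every artifact is reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 36L, n_regions = 268L,
                             n_timepoints = 197L, tr_seconds = 2,
                             band_hz = c(0.009, 0.08), n_components = 4L,
                             effect_size = 2, noise_sd = 1,
                             behavior_gap = 4,
                             behavior_sd = c(st = 50, ns = 1500),
                             effect_mode = c("dynamic", "static"),
                             seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 4L || n_subjects %% 2L != 0L) {
    dc_stop("n_subjects must be an even number >= 4 (balanced design)",
            "dynconn_configuration_error")
  }
  if (n_components < 1L) {
    dc_stop("n_components must be >= 1", "dynconn_configuration_error")
  }
  if (effect_size < 0 || noise_sd <= 0 || behavior_gap <= 0) {
    dc_stop("effect_size must be >= 0; noise_sd and behavior_gap positive",
            "dynconn_configuration_error")
  }
  check_band(band_hz, n_timepoints, tr_seconds)
  structure(
    list(n_subjects = n_subjects, n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
         band_hz = band_hz, n_components = as.integer(n_components),
         effect_size = effect_size, noise_sd = noise_sd,
         behavior_gap = behavior_gap, behavior_sd = behavior_sd,
         effect_mode = effect_mode, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

check_band <- function(band_hz, n_timepoints, tr_seconds) {
  nyquist <- 1 / (2 * tr_seconds)
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] >= nyquist ||
      band_hz[1] >= band_hz[2]) {
    dc_stop(sprintf("band must satisfy 0 < low < high < Nyquist (%g Hz)",
                    nyquist), "dynconn_range_error")
  }
  if (length(band_bins(n_timepoints, band_hz, tr_seconds)) == 0L) {
    dc_stop("passband contains no DFT bins at this length/TR",
            "dynconn_range_error")
  }
  invisible(TRUE)
}

# Positive-frequency DFT bin indices (1-based k+1 for frequency k/(n*tr))
# inside the band.
band_bins <- function(n, band_hz, tr_seconds) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr_seconds)
  k[f >= band_hz[1] & f <= band_hz[2]]
}

# Project the columns of x onto the passband by zeroing out-of-band DFT
# coefficients (the positive bins and their conjugate mirrors are kept).
band_project <- function(x, band_hz, tr_seconds) {
  n <- nrow(x)
  keep <- band_bins(n, band_hz, tr_seconds)
  mask <- rep(0, n)
  mask[keep + 1L] <- 1
  mask[n - keep + 1L] <- 1
  z <- stats::mvfft(x) * mask
  Re(stats::mvfft(z, inverse = TRUE)) / n
}

#' Generate band-limited noise series
#'
#' White Gaussian noise is masked in the frequency domain to the passband
#' and each column is standardized to mean 0, variance 1 (sample
#' convention). Power outside the band is numerically zero.
#'
#' @param n_timepoints Number of time points.
#' @param n_series Number of columns.
#' @param band_hz Passband `(low, high)` in Hz.
#' @param tr_seconds Sampling interval in seconds.
#' @param seed Optional seed; when given, the caller's RNG stream is left
#'   untouched.
#' @return `n_timepoints` x `n_series` numeric matrix.
#' @export
generate_band_limited_noise <- function(n_timepoints, n_series,
                                        band_hz = c(0.009, 0.08),
                                        tr_seconds = 2, seed = NULL) {
  check_band(band_hz, n_timepoints, tr_seconds)
  gen <- function() {
    x <- matrix(stats::rnorm(n_timepoints * n_series), n_timepoints, n_series)
    x <- band_project(x, band_hz, tr_seconds)
    x <- sweep(x, 2L, colMeans(x), "-")
    sdev <- apply(x, 2L, stats::sd)
    sweep(x, 2L, sdev, "/")
  }
  if (is.null(seed)) gen() else with_seed_local(seed, gen())
}

# Disjoint-support, non-negative, unit-norm spatial patterns: component k
# loads a contiguous block of regions (random region permutation) with
# |N(1, 0.3)| weights. Disjoint supports make the patterns exactly
# orthonormal.
make_patterns <- function(n_regions, n_components) {
  perm <- sample.int(n_regions)
  sizes <- rep(floor(n_regions / n_components), n_components)
  U <- matrix(0, n_regions, n_components)
  offset <- 0L
  for (k in seq_len(n_components)) {
    idx <- perm[(offset + 1L):(offset + sizes[k])]
    w <- abs(stats::rnorm(sizes[k], mean = 1, sd = 0.3))
    U[idx, k] <- w / sqrt(sum(w^2))
    offset <- offset + sizes[k]
  }
  U
}

#' Generate a synthetic cohort
#'
#' Draws the planted spatial patterns, balanced group labels, per-subject
#' signals and behavioral records described in the package's data model
#' (see the methods vignette). Subject `i`'s data are
#' `sum_k a_k(t; group) s_ik(t) w_k' + noise`, where `s_ik` are
#' band-limited latents, `w_k = sqrt(N) u_k` the scaled planted patterns,
#' and the high-improvement group's envelopes `a_k(t)` carry an extra
#' slowly varying term proportional to `effect_size`. The composed matrix
#' is re-projected onto the passband, so every emitted signal is strictly
#' band-limited.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_cohort`: `timeseries` (named list
#'   of [subject_timeseries()]), `manifest` (tibble in the cohort-manifest
#'   layout, `timeseries_path` filled by [write_cohort()]), `ground_truth`
#'   (planted patterns, groups, envelopes, generator settings), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  with_seed_local(cf$seed, {
    N <- cf$n_regions; Tt <- cf$n_timepoints; K <- cf$n_components
    U <- make_patterns(N, K)
    Wp <- sqrt(N) * U  # per-region amplitudes of order 1 on the support
    scales <- 1 / sqrt(seq_len(K))

    ids <- sprintf("S%02d", seq_len(cf$n_subjects))
    groups <- stats::setNames(
      sample(rep(c("low", "high"), cf$n_subjects / 2L)), ids)

    # Group-contrast envelopes: slow raised sinusoids in [0, 1].
    tsec <- (seq_len(Tt) - 1L) * cf$tr_seconds
    f_mod <- stats::runif(K, 0.010, 0.025)
    phase <- stats::runif(K, 0, 2 * pi)
    d <- vapply(seq_len(K), function(k) {
      if (cf$effect_mode == "static") rep(0.5, Tt)
      else 0.5 * (1 + sin(2 * pi * f_mod[k] * tsec + phase[k]))
    }, numeric(Tt))
    amp <- list(
      low  = vapply(seq_len(K), function(k) rep(scales[k], Tt), numeric(Tt)),
      high = vapply(seq_len(K), function(k)
        scales[k] * (1 + cf$effect_size * d[, k]), numeric(Tt)))

    timeseries <- vector("list", cf$n_subjects)
    names(timeseries) <- ids
    for (i in seq_len(cf$n_subjects)) {
      a <- amp[[groups[ids[i]]]]
      s <- generate_band_limited_noise(Tt, K, cf$band_hz, cf$tr_seconds)
      X <- (a * s) %*% t(Wp) +
        cf$noise_sd * generate_band_limited_noise(Tt, N, cf$band_hz,
                                                  cf$tr_seconds)
      X <- band_project(X, cf$band_hz, cf$tr_seconds)
      timeseries[[i]] <- subject_timeseries(X, subject_id = ids[i],
                                            tr_seconds = cf$tr_seconds)
    }

    # Behavioral records: the high-improvement group sits less and steps
    # more; means are +/- behavior_gap/2 within-group SDs.
    g_high <- groups == "high"
    st_mu <- ifelse(g_high, -1, 1) * cf$behavior_gap / 2 * cf$behavior_sd["st"]
    ns_mu <- ifelse(g_high, 1, -1) * cf$behavior_gap / 2 * cf$behavior_sd["ns"]
    st_change <- stats::rnorm(cf$n_subjects, st_mu, cf$behavior_sd["st"])
    ns_change <- stats::rnorm(cf$n_subjects, ns_mu, cf$behavior_sd["ns"])
    st_base <- pmax(stats::rnorm(cf$n_subjects, 570, 110), 300)
    ns_base <- pmax(stats::rnorm(cf$n_subjects, 7000, 2000), 3000)
    manifest <- tibble::tibble(
      subject_id = ids,
      timeseries_path = NA_character_,
      st_baseline = st_base,
      st_6mo = pmax(st_base + st_change, 0),
      ns_baseline = ns_base,
      ns_6mo = pmax(ns_base + ns_change, 0))

    structure(
      list(timeseries = timeseries,
           manifest = manifest,
           ground_truth = list(patterns = U, component_scales = scales,
                               groups = groups, envelopes = amp,
                               modulation_hz = f_mod,
                               modulation_phase = phase),
           config = cf),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "<synthetic_cohort> %d subjects x %d regions x %d time points (effect size %g, %d components, seed %d)\n",
    cf$n_subjects, cf$n_regions, cf$n_timepoints, cf$effect_size,
    cf$n_components, cf$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one time-series TSV per subject, `manifest.csv`, `atlas.csv`
#' (synthetic region metadata: grid MNI-like coordinates, round-robin
#' subnetwork assignment), and `ground_truth.json`.
#'
#' @param cohort A [generate_cohort()] output.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$timeseries)
  paths <- file.path(dir, paste0(ids, ".tsv"))
  for (i in seq_along(ids)) {
    write_subject_timeseries(cohort$timeseries[[i]], paths[i])
  }
  manifest <- cohort$manifest
  manifest$timeseries_path <- paste0(ids, ".tsv")
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  N <- cohort$config$n_regions
  grid <- expand.grid(x = seq(-60, 60, length.out = ceiling(N^(1 / 3))),
                      y = seq(-80, 60, length.out = ceiling(N^(1 / 3))),
                      z = seq(-40, 70, length.out = ceiling(N^(1 / 3))))
  atlas <- tibble::tibble(
    region_id = seq_len(N),
    label = sprintf("synthetic_region_%03d", seq_len(N)),
    x = round(grid$x[seq_len(N)], 1),
    y = round(grid$y[seq_len(N)], 1),
    z = round(grid$z[seq_len(N)], 1),
    subnetwork = rep_len(SUBNETWORKS, N))
  write_atlas_info(atlas, file.path(dir, "atlas.csv"))
  jsonlite::write_json(
    list(groups = as.list(cohort$ground_truth$groups),
         component_scales = cohort$ground_truth$component_scales,
         modulation_hz = cohort$ground_truth$modulation_hz,
         patterns = cohort$ground_truth$patterns,
         config = unclass(cohort$config)),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(manifest_path)
}
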