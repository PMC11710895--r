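# Shared fixtures. Expensive objects (study-scale cohorts and tensors) are
# memoised per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Desk-scale analogue of the study cohort: 36 subjects, 80 regions, 197 time
# points, 4 planted components.
study_cohort <- function(effect_size = 2, seed = 20240917 %% 1000003) {
  cached(sprintf("cohort_e%g_s%d", effect_size, seed), {
    generate_cohort(synthetic_config(
      n_subjects = 36, n_regions = 80, n_timepoints = 197,
      effect_size = effect_size, seed = seed))
  })
}

study_tensors <- function(effect_size = 2, seed = 20240917 %% 1000003) {
  cached(sprintf("tensors_e%g_s%d", effect_size, seed), {
    build_cohort_networks(study_cohort(effect_size, seed),
                          check_f_min = FALSE)
  })
}

study_labels <- function(measure = "st", effect_size = 2,
                         seed = 20240917 %% 1000003) {
  median_split_groups(
    behavior_records(study_cohort(effect_size, seed)$manifest, measure))
}

# A small cohort for fast prediction-level tests: 12 subjects, 16 regions,
# 60 time points, windows of 20 TRs.
small_cohort <- function(effect_size = 2, seed = 78) {
  cached(sprintf("small_cohort_e%g_s%d", effect_size, seed), {
    generate_cohort(synthetic_config(
      n_subjects = 12, n_regions = 16, n_timepoints = 60,
      n_components = 2, effect_size = effect_size, seed = seed))
  })
}

small_tensors <- function(effect_size = 2, seed = 78) {
  cached(sprintf("small_tensors_e%g_s%d", effect_size, seed), {
    build_cohort_networks(small_cohort(effect_size, seed),
                          spec = window_spec(length_trs = 20),
                          density = 0.2, check_f_min = FALSE)
  })
}

small_setup <- function(effect_size = 2, seed = 78, n_splits = 25) {
  lab <- median_split_groups(
    behavior_records(small_cohort(effect_size, seed)$manifest, "st"))
  scheme <- make_split_scheme(lab, n_splits = n_splits, n_train = 8,
                              n_test = 4, seed = 99)
  list(tensors = small_tensors(effect_size, seed), labels = lab,
       scheme = scheme)
}

# Wrap an N x N x T array of symmetric zero-diagonal slices as a tensor
# object (for decomposition tests that plant exact structure).
fake_tensor <- function(arr, subject_id = "X", density = 1) {
  structure(
    list(subject_id = subject_id, data = arr, density = density,
         window = window_spec(length_trs = 2), rank_by = "signed",
         binarize = FALSE),
    class = "dynamic_connectivity_tensor")
}

# Random thresholded-correlation-like stack for SVD oracle tests.
random_stack <- function(N, T, M, density = 0.5) {
  tensors <- lapply(seq_len(M), function(m) {
    arr <- array(0, dim = c(N, N, T))
    for (k in seq_len(T)) {
      A <- matrix(rnorm(N * N), N, N)
      S <- (A + t(A)) / 2
      diag(S) <- 0
      arr[, , k] <- proportional_threshold(S, density)
    }
    fake_tensor(arr, subject_id = sprintf("M%02d", m), density = density)
  })
  stack_training_tensors(tensors)
}

# Mode-1 unfolding of a stack's dense array: N x (N*T*M).
mode1_unfolding <- function(stack) {
  arr <- as.array(stack)
  d <- dim(arr)
  matrix(arr, nrow = d[1])
}

# Behavior records straight from vectors.
records_from_changes <- function(changes, measure = "st",
                                 ids = sprintf("S%02d", seq_along(changes))) {
  tibble::tibble(subject_id = ids, measure = measure,
                 baseline = 0, month6 = changes, change = changes)
}

# Component map built straight from a loading vector.
new_map_for_test <- function(loading, index = 1L) {
  structure(
    list(index = index, loading = loading,
         edge_matrix = tcrossprod(loading),
         normalized_variance = 1, top_edges = NULL, node_degrees = NULL),
    class = "component_map")
}
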