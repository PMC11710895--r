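# HOSVD-based reduction of stacked connectivity tensors.
#
# The training subjects' N x N x T tensors are concatenated along a fourth
# (subject) mode; the connectivity-mode basis U is the left singular factor
# of the mode-1 unfolding (N x N*T*M). Because every slice is symmetric the
# mode-2 factor coincides with the mode-1 factor, so a single U reduces both
# connectivity modes: each slice C_t maps to U' C_t U. The time and subject
# modes are deliberately left unreduced -- only U enters downstream
# quantities. U is computed from the N x N Gram matrix G = sum over all
# slices of C C' ( = C^2 by symmetry) via a symmetric eigendecomposition,
# which equals the unfolding SVD without materializing the unfolding.

#' Stack per-subject connectivity tensors along a subject mode
#'
#' Validates that all tensors share dimensions and threshold density and
#' records the subject order (= the stack's fourth-mode order). The slices
#' are kept per subject rather than materialized as a dense N x N x T x M
#' array; [as.array()] converts small stacks for cross-checking.
#'
#' @param tensors List of >= 2 [build_dynamic_networks()] outputs.
#' @return An object of class `stacked_connectivity_tensor`.
#' @export
stack_training_tensors <- function(tensors) {
  if (length(tensors) < 2L) {
    dc_stop("need at least 2 tensors to stack", "dynconn_size_error")
  }
  ok <- vapply(tensors, inherits, logical(1), "dynamic_connectivity_tensor")
  if (!all(ok)) {
    dc_stop("all elements must be dynamic_connectivity_tensor objects",
            "dynconn_validation_error")
  }
  dims <- vapply(tensors, function(x) dim(x$data), numeric(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[3, ] != dims[3, 1])) {
    dc_stop("all tensors must share N and T", "dynconn_dimension_error")
  }
  dens <- vapply(tensors, function(x) x$density, numeric(1))
  if (any(abs(dens - dens[1]) > 1e-12)) {
    dc_stop("all tensors must share the threshold density",
            "dynconn_dimension_error")
  }
  structure(
    list(tensors = tensors,
         subject_ids = vapply(tensors, function(x) x$subject_id, character(1)),
         n_regions = dims[1, 1], n_windows = dims[3, 1],
         n_subjects = length(tensors), density = dens[1]),
    class = "stacked_connectivity_tensor"
  )
}

#' @export
print.stacked_connectivity_tensor <- function(x, ...) {
  cat(sprintf("<stacked_connectivity_tensor> %d x %d x %d x %d (N x N x T x M)\n",
              x$n_regions, x$n_regions, x$n_windows, x$n_subjects))
  invisible(x)
}

#' @export
as.array.stacked_connectivity_tensor <- function(x, ...) {
  arr <- array(0, dim = c(x$n_regions, x$n_regions, x$n_windows, x$n_subjects))
  for (m in seq_len(x$n_subjects)) arr[, , , m] <- x$tensors[[m]]$data
  arr
}

# Mode-1 Gram matrix of a stack: sum over all (t, m) slices of C %*% t(C).
stack_gram <- function(stack) {
  G <- matrix(0, stack$n_regions, stack$n_regions)
  for (tn in stack$tensors) G <- G + tensor_gram(tn)
  G
}

# Gram contribution of one subject tensor (used for per-split sums).
tensor_gram <- function(tensor) {
  d <- dim(tensor$data)
  G <- matrix(0, d[1], d[1])
  for (k in seq_len(d[3])) {
    C <- tensor$data[, , k]
    G <- G + tcrossprod(C)
  }
  G
}

# Mean slice over time of one subject tensor.
tensor_mean_slice <- function(tensor) {
  d <- dim(tensor$data)
  rowMeans(array(tensor$data, dim = c(d[1] * d[2], d[3])), dims = 1) |>
    matrix(nrow = d[1], ncol = d[2])
}

# Deterministic sign convention: each column's largest-magnitude entry is
# positive (first such entry on ties).
fix_column_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Fit the connectivity-mode HOSVD basis
#'
#' Computes the left singular vectors/values of the mode-1 unfolding of the
#' stacked training tensor and selects the rank as the smallest R whose
#' leading singular values capture at least `variance_threshold` of the
#' total squared singular value mass (the study criterion is > 85%
#' variance). A fixed `rank` overrides the variance criterion (the study's
#' fixed R = 17). Sign convention: each basis column's largest-magnitude
#' entry is positive, making the factorization deterministic.
#'
#' @param stack A [stack_training_tensors()] output.
#' @param variance_threshold Cumulative variance fraction in (0, 1]
#'   (default 0.85).
#' @param rank Optional fixed rank overriding the variance criterion.
#' @return An object of class `connectivity_basis`: `basis` (N x R,
#'   orthonormal columns), `singular_values` (length N, non-increasing),
#'   `variance_fractions` (cumulative), `rank`, `training_ids`.
#' @export
fit_connectivity_basis <- function(stack, variance_threshold = 0.85,
                                   rank = NULL) {
  stopifnot(inherits(stack, "stacked_connectivity_tensor"))
  if (variance_threshold <= 0 || variance_threshold > 1) {
    dc_stop("variance_threshold must lie in (0, 1]", "dynconn_range_error")
  }
  G <- stack_gram(stack)
  basis_from_gram(G, variance_threshold, rank, stack$subject_ids,
                  stack$n_regions)
}

# Shared by fit_connectivity_basis and the per-split CV engine.
basis_from_gram <- function(G, variance_threshold, rank, training_ids, N) {
  if (max(abs(G)) == 0) {
    dc_stop("all-zero connectivity stack; cannot fit a basis",
            "dynconn_degenerate_input_error")
  }
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  sv <- sqrt(pmax(eg$values, 0))
  U <- fix_column_signs(eg$vectors)
  fractions <- cumsum(sv^2) / sum(sv^2)
  R <- if (is.null(rank)) select_rank(sv, variance_threshold) else as.integer(rank)
  if (R < 1L || R > N) {
    dc_stop(sprintf("rank must lie in 1..%d", N), "dynconn_range_error")
  }
  structure(
    list(basis = U[, seq_len(R), drop = FALSE],
         singular_values = sv,
         variance_fractions = fractions,
         rank = R,
         variance_threshold = variance_threshold,
         training_ids = training_ids),
    class = "connectivity_basis"
  )
}

#' @export
print.connectivity_basis <- function(x, ...) {
  cat(sprintf(
    "<connectivity_basis> %d regions, rank %d (%.1f%% variance captured), %d training subjects\n",
    nrow(x$basis), x$rank, 100 * x$variance_fractions[x$rank],
    length(x$training_ids)))
  invisible(x)
}

#' Minimal rank capturing a variance fraction
#'
#' Returns the smallest `R` such that `sum(s[1:R]^2) / sum(s^2) >=
#' variance_threshold`.
#'
#' @param singular_values Non-increasing, non-negative vector with at least
#'   one positive entry.
#' @param variance_threshold Fraction in (0, 1].
#' @return Integer rank.
#' @export
select_rank <- function(singular_values, variance_threshold) {
  s <- singular_values
  if (length(s) == 0L || any(s < 0) || all(s == 0)) {
    dc_stop("singular values must be non-negative with at least one positive",
            "dynconn_degenerate_input_error")
  }
  if (any(diff(s) > 1e-8 * max(s))) {
    dc_stop("singular values must be non-increasing",
            "dynconn_validation_error")
  }
  if (variance_threshold <= 0 || variance_threshold > 1) {
    dc_stop("variance_threshold must lie in (0, 1]", "dynconn_range_error")
  }
  fractions <- cumsum(s^2) / sum(s^2)
  as.integer(which(fractions >= variance_threshold - 1e-12)[1L])
}

#' Project a subject tensor onto the connectivity basis
#'
#' Maps each time slice `C_t` to `U' C_t U` (both connectivity modes reduced
#' by the training basis). Test subjects are projected with the basis fitted
#' on training subjects only — the basis is never recomputed here.
#'
#' @param tensor A [build_dynamic_networks()] output.
#' @param basis A [fit_connectivity_basis()] output with matching N.
#' @return R x R x T numeric array.
#' @export
project_subject <- function(tensor, basis) {
  stopifnot(inherits(tensor, "dynamic_connectivity_tensor"),
            inherits(basis, "connectivity_basis"))
  d <- dim(tensor$data)
  if (d[1] != nrow(basis$basis)) {
    dc_stop(sprintf("tensor has %d regions but basis has %d rows",
                    d[1], nrow(basis$basis)), "dynconn_dimension_error")
  }
  U <- basis$basis
  R <- ncol(U)
  out <- array(0, dim = c(R, R, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- crossprod(U, tensor$data[, , k]) %*% U
  }
  out
}

#' Time-average a reduced tensor into a feature vector
#'
#' Entrywise mean of the R x R x T reduced tensor over the time mode; the
#' features are the row-major flattening of the resulting R x R matrix
#' (length R^2; 289 at the study rank R = 17).
#'
#' @param reduced R x R x T numeric array from [project_subject()].
#' @param subject_id Subject identifier to attach.
#' @return An object of class `reduced_features`: `subject_id`, `reduced`
#'   (R x R), `features` (length R^2).
#' @export
time_average_features <- function(reduced, subject_id) {
  if (!is.array(reduced) || length(dim(reduced)) != 3L ||
      dim(reduced)[1] != dim(reduced)[2]) {
    dc_stop("`reduced` must be an R x R x T array", "dynconn_dimension_error")
  }
  d <- dim(reduced)
  avg <- matrix(rowMeans(array(reduced, dim = c(d[1] * d[2], d[3]))),
                nrow = d[1], ncol = d[2])
  structure(
    list(subject_id = subject_id, reduced = avg, features = as.vector(t(avg))),
    class = "reduced_features"
  )
}

#' Normalized component variances
#'
#' `nv_i = sigma_i^2 / sigma_1^2`: each component's variance relative to the
#' leading component's. `nv_1 = 1` and the sequence is non-increasing; the
#' study ranks network components by this quantity (components below 0.25
#' are not displayed).
#'
#' @param basis A [fit_connectivity_basis()] output.
#' @return Numeric vector, same length as `singular_values`.
#' @export
normalized_variances <- function(basis) {
  s <- basis$singular_values
  if (s[1] <= 0) {
    dc_stop("leading singular value must be positive",
            "dynconn_degenerate_input_error")
  }
  s^2 / s[1]^2
}

new_component_map <- function(loading, index, normalized_variance) {
  structure(
    list(index = index,
         loading = loading,
         edge_matrix = tcrossprod(loading),
         normalized_variance = normalized_variance,
         top_edges = NULL,
         node_degrees = NULL),
    class = "component_map"
  )
}

#' Reconstruct a network component from its singular vector
#'
#' The component's brain-space map is the rank-1 edge matrix `u u'` built
#' from basis column `index`, carrying that component's normalized variance.
#'
#' @param basis A [fit_connectivity_basis()] output.
#' @param index Component index in `1..rank`.
#' @return An object of class `component_map`.
#' @export
reconstruct_component <- function(basis, index) {
  stopifnot(inherits(basis, "connectivity_basis"))
  index <- as.integer(index)
  if (index < 1L || index > basis$rank) {
    dc_stop(sprintf("component index must lie in 1..%d", basis$rank),
            "dynconn_range_error")
  }
  new_component_map(basis$basis[, index], index, normalized_variances(basis)[index])
}

#' Average one component across repeated-split bases
#'
#' Singular vectors are sign-ambiguous; before averaging, each basis's
#' column `index` is flipped to have non-negative dot product with the first
#' basis's column, then the aligned vectors are averaged and renormalized to
#' unit length. The attached normalized variance is the mean across bases.
#'
#' @param bases Non-empty list of [fit_connectivity_basis()] outputs sharing
#'   N and `rank >= index`.
#' @param index Component index.
#' @return An object of class `component_map` built from the averaged
#'   loading.
#' @export
average_components_across_splits <- function(bases, index) {
  if (length(bases) == 0L) {
    dc_stop("need at least one basis", "dynconn_size_error")
  }
  index <- as.integer(index)
  cols <- lapply(bases, function(b) {
    stopifnot(inherits(b, "connectivity_basis"))
    if (index > b$rank) {
      dc_stop(sprintf("basis rank %d < component index %d", b$rank, index),
              "dynconn_range_error")
    }
    b$basis[, index]
  })
  ref <- cols[[1L]]
  aligned <- lapply(cols, function(u) if (sum(u * ref) < 0) -u else u)
  avg <- Reduce(`+`, aligned) / length(aligned)
  nrm <- sqrt(sum(avg^2))
  if (nrm == 0) {
    dc_stop("averaged loading is zero; components do not align",
            "dynconn_degenerate_input_error")
  }
  nv <- mean(vapply(bases, function(b) normalized_variances(b)[index],
                    numeric(1)))
  new_component_map(avg / nrm, index, nv)
}

#' Threshold a component map to its strongest edges
#'
#' Keeps the `round(top_fraction * N(N-1)/2)` upper-triangle entries of
#' `|edge_matrix|` with the largest magnitude (ties by ascending (row,
#' column) index; the study displays the top 1%) and computes per-region
#' degrees over the retained edges.
#'
#' @param map A `component_map`.
#' @param top_fraction Fraction of undirected edges to keep, in (0, 1].
#' @return The map with `top_edges` (tibble `region_i`, `region_j`,
#'   `weight`) and `node_degrees` (integer vector) filled in.
#' @export
threshold_component_edges <- function(map, top_fraction = 0.01) {
  stopifnot(inherits(map, "component_map"))
  if (top_fraction <= 0 || top_fraction > 1) {
    dc_stop("top_fraction must lie in (0, 1]", "dynconn_range_error")
  }
  n <- nrow(map$edge_matrix)
  pairs <- upper_tri_pairs(n)
  vals <- map$edge_matrix[cbind(pairs$i, pairs$j)]
  K <- as.integer(round_half_up(top_fraction * n_undirected_edges(n)))
  keep <- order(-abs(vals), pairs$i, pairs$j)[seq_len(K)]
  map$top_edges <- tibble::tibble(
    region_i = pairs$i[keep], region_j = pairs$j[keep], weight = vals[keep])
  deg <- tabulate(c(pairs$i[keep], pairs$j[keep]), nbins = n)
  map$node_degrees <- as.integer(deg)
  map
}

#' @export
print.component_map <- function(x, ...) {
  cat(sprintf("<component_map> component %d (normalized variance %.3f)",
              x$index, x$normalized_variance))
  if (!is.null(x$top_edges)) {
    cat(sprintf(", %d retained edges", nrow(x$top_edges)))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a connectivity basis into a component table
#' @param x A `connectivity_basis`.
#' @param ... Unused.
#' @return Tibble with `component`, `singular_value`,
#'   `cumulative_variance`, `normalized_variance`.
#' @method tidy connectivity_basis
#' @export
tidy.connectivity_basis <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$singular_values),
    singular_value = x$singular_values,
    cumulative_variance = x$variance_fractions,
    normalized_variance = normalized_variances(x))
}
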