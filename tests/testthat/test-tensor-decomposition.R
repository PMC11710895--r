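# HOSVD basis fitting, rank selection, projection, and component maps.

test_that("stacking validates shapes and records subject order", {
  st <- random_stack(4, 3, 2)
  expect_equal(st$n_regions, 4L)
  expect_equal(st$n_windows, 3L)
  expect_equal(st$subject_ids, c("M01", "M02"))
  expect_equal(dim(as.array(st)), c(4, 4, 3, 2))

  t1 <- fake_tensor(array(0, c(4, 4, 3)))
  t2 <- fake_tensor(array(0, c(4, 4, 2)))
  expect_error(stack_training_tensors(list(t1, t2)),
               class = "dynconn_dimension_error")
  expect_error(stack_training_tensors(list(t1)), class = "dynconn_size_error")
})

test_that("the Gram-based basis matches an explicit mode-1 unfolding SVD", {
  set.seed(20)
  for (i in 1:20) {
    N <- sample(4:8, 1); T <- sample(2:5, 1); M <- sample(2:4, 1)
    st <- random_stack(N, T, M)
    basis <- fit_connectivity_basis(st, rank = N)
    sv_oracle <- svd(mode1_unfolding(st))
    expect_equal(basis$singular_values, sv_oracle$d, tolerance = 1e-8)
    # subspaces compared through projectors at well-separated cut points
    gaps <- which(abs(diff(sv_oracle$d)) > 1e-6 * sv_oracle$d[1])
    for (r in head(gaps, 3)) {
      P_pkg <- tcrossprod(basis$basis[, 1:r, drop = FALSE])
      P_ora <- tcrossprod(sv_oracle$u[, 1:r, drop = FALSE])
      expect_equal(P_pkg, P_ora, tolerance = 1e-8)
    }
    expect_equal(crossprod(basis$basis), diag(N), tolerance = 1e-10)
  }
})

test_that("a rank-1 planted stack yields rank 1 and recovers its pattern", {
  set.seed(21)
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  sl <- tcrossprod(u)
  arr <- array(rep(sl, 4), c(6, 6, 4))
  st <- stack_training_tensors(list(fake_tensor(arr, "A"),
                                    fake_tensor(arr, "B")))
  basis <- fit_connectivity_basis(st, variance_threshold = 0.85)
  expect_equal(basis$rank, 1L)
  expect_equal(abs(sum(basis$basis[, 1] * u)), 1, tolerance = 1e-10)
  expect_error(
    fit_connectivity_basis(stack_training_tensors(list(
      fake_tensor(array(0, c(3, 3, 2))), fake_tensor(array(0, c(3, 3, 2)))))),
    class = "dynconn_degenerate_input_error")
})

test_that("select_rank returns the minimal variance-capturing rank", {
  expect_equal(select_rank(c(3, 0, 0), 0.85), 1L)
  # squared proportions 0.5, 0.2, 0.2, 0.1 -> cumulative 0.5, 0.7, 0.9
  s <- sqrt(c(0.5, 0.2, 0.2, 0.1))
  expect_equal(select_rank(s, 0.85), 3L)
  expect_equal(select_rank(c(5, 4, 3, 2, 0, 0), 1.0), 4L)

  # brute-force minimality over random spectra
  set.seed(22)
  for (i in 1:50) {
    s <- sort(abs(rnorm(sample(3:12, 1))), decreasing = TRUE)
    thr <- runif(1, 0.1, 0.999)
    r <- select_rank(s, thr)
    frac <- cumsum(s^2) / sum(s^2)
    oracle <- min(which(frac >= thr))
    expect_equal(r, oracle)
  }
  expect_error(select_rank(c(0, 0), 0.85),
               class = "dynconn_degenerate_input_error")
})

test_that("projection contracts norms and is lossless at full rank", {
  set.seed(23)
  st <- random_stack(6, 4, 3)
  tensor <- st$tensors[[1]]

  full <- fit_connectivity_basis(st, rank = 6)
  red_full <- project_subject(tensor, full)
  U <- full$basis
  for (k in 1:4) {
    recon <- U %*% red_full[, , k] %*% t(U)
    expect_equal(recon, tensor$data[, , k], tolerance = 1e-10)
  }

  low <- fit_connectivity_basis(st, rank = 2)
  red_low <- project_subject(tensor, low)
  for (k in 1:4) {
    expect_lte(sqrt(sum(red_low[, , k]^2)),
               sqrt(sum(tensor$data[, , k]^2)) + 1e-12)
    # definition check against explicit matrix products
    expect_equal(red_low[, , k],
                 t(low$basis) %*% tensor$data[, , k] %*% low$basis,
                 tolerance = 1e-12)
  }

  # a slice lying in the basis span keeps its norm
  u1 <- full$basis[, 1]
  planted <- fake_tensor(array(tcrossprod(u1), c(6, 6, 1)))
  red <- project_subject(planted, full)
  expect_equal(sqrt(sum(red^2)), 1, tolerance = 1e-10)
})

test_that("time averaging flattens row-major and cancels opposite slices", {
  A <- matrix(c(1, 2, 2, 4), 2, 2)
  one <- time_average_features(array(A, c(2, 2, 1)), "S")
  expect_equal(one$reduced, A)
  expect_equal(one$features, c(1, 2, 2, 4))  # row-major of symmetric A

  # explicit row-major order on an asymmetric matrix
  B <- matrix(1:4, 2, 2)  # columns (1,2), (3,4)
  rf <- time_average_features(array(B, c(2, 2, 1)), "S")
  expect_equal(rf$features, c(1, 3, 2, 4))

  pm <- array(c(A, -A), c(2, 2, 2))
  expect_equal(time_average_features(pm, "S")$reduced, matrix(0, 2, 2))

  r17 <- time_average_features(array(rnorm(17 * 17 * 3), c(17, 17, 3)), "S")
  expect_length(r17$features, 289L)
})

test_that("reconstructed components are unit-trace rank-1 outer products", {
  st <- cached("decomp_stack", random_stack(8, 3, 2))
  basis <- fit_connectivity_basis(st, rank = 4)
  cm <- reconstruct_component(basis, 2)
  expect_equal(cm$edge_matrix, tcrossprod(basis$basis[, 2]))
  expect_equal(sum(diag(cm$edge_matrix)), 1, tolerance = 1e-10)
  expect_equal(qr(cm$edge_matrix)$rank, 1L)
  expect_error(reconstruct_component(basis, 5), class = "dynconn_range_error")

  # sign symmetry of the outer product
  flipped <- basis
  flipped$basis[, 2] <- -flipped$basis[, 2]
  expect_equal(reconstruct_component(flipped, 2)$edge_matrix, cm$edge_matrix)
})

test_that("cross-split component averaging aligns signs before averaging", {
  st <- cached("decomp_stack", random_stack(8, 3, 2))
  basis <- fit_connectivity_basis(st, rank = 3)
  flipped <- basis
  flipped$basis <- -flipped$basis
  avg <- average_components_across_splits(list(basis, flipped), 1)
  expect_equal(abs(sum(avg$loading * basis$basis[, 1])), 1, tolerance = 1e-10)

  same <- average_components_across_splits(rep(list(basis), 100), 2)
  expect_equal(same$loading, basis$basis[, 2], tolerance = 1e-12)

  # averaging noisy copies of a common loading improves recovery on average
  set.seed(24)
  u <- rnorm(8); u <- u / sqrt(sum(u^2))
  noisy <- lapply(1:30, function(i) {
    v <- u + rnorm(8, sd = 0.3)
    v <- v / sqrt(sum(v^2))
    b <- basis
    b$basis[, 1] <- v * sample(c(-1, 1), 1)
    b
  })
  avg_n <- average_components_across_splits(noisy, 1)
  cos_avg <- abs(sum(avg_n$loading * u))
  cos_each <- vapply(noisy, function(b) abs(sum(b$basis[, 1] * u)), numeric(1))
  expect_gt(cos_avg, mean(cos_each))
})

test_that("component edge maps keep the top fraction and count degrees", {
  st <- cached("decomp_stack", random_stack(8, 3, 2))
  basis <- fit_connectivity_basis(st, rank = 2)
  cm <- threshold_component_edges(reconstruct_component(basis, 1), 0.25)
  K <- floor(0.25 * 28 + 0.5)
  expect_equal(nrow(cm$top_edges), K)
  expect_equal(sum(cm$node_degrees), 2L * K)
  # retained edges are the K largest |edge_matrix| entries
  pairs <- which(upper.tri(cm$edge_matrix), arr.ind = TRUE)
  vals <- abs(cm$edge_matrix[pairs])
  expect_equal(sort(abs(cm$top_edges$weight), decreasing = TRUE),
               sort(vals, decreasing = TRUE)[seq_len(K)], tolerance = 1e-12)

  # star-structured loading: the hub has the highest degree
  hub <- c(3, rep(0.4, 5))
  hub_map <- threshold_component_edges(
    new_map_for_test(hub / sqrt(sum(hub^2))), 0.3)
  expect_equal(which.max(hub_map$node_degrees), 1L)

  # degenerate loading e1: all off-diagonal mass zero; ties fill to 2K
  e1 <- c(1, rep(0, 7))
  deg_map <- threshold_component_edges(new_map_for_test(e1), 0.25)
  expect_equal(nrow(deg_map$top_edges), floor(0.25 * 28 + 0.5))
  expect_equal(sum(deg_map$node_degrees), 2L * nrow(deg_map$top_edges))
})

test_that("normalized variances are relative to the leading component", {
  st <- cached("decomp_stack", random_stack(8, 3, 2))
  basis <- fit_connectivity_basis(st, rank = 3)
  nv <- normalized_variances(basis)
  expect_equal(nv[1], 1)
  expect_true(all(diff(nv) <= 1e-12))

  b2 <- basis
  b2$singular_values <- c(2, 1)
  expect_equal(normalized_variances(b2), c(1, 0.25))

  # planted two-component stack with 4:1 energy ratio -> nv2 = 0.25
  set.seed(25)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:2]
  arr <- array(0, c(6, 6, 5))
  c1 <- rnorm(5); c2 <- rnorm(5)
  c1 <- c1 * sqrt(4 * sum(c2^2) / sum(c1^2))  # exact 4:1 energy
  for (k in 1:5) {
    arr[, , k] <- c1[k] * tcrossprod(Q[, 1]) + c2[k] * tcrossprod(Q[, 2])
  }
  st2 <- stack_training_tensors(list(fake_tensor(arr, "A"),
                                     fake_tensor(arr, "B")))
  b3 <- fit_connectivity_basis(st2, rank = 2)
  expect_equal(normalized_variances(b3)[2], 0.25, tolerance = 1e-8)
})

test_that("basis tidier exposes the component table", {
  st <- cached("decomp_stack", random_stack(8, 3, 2))
  basis <- fit_connectivity_basis(st, rank = 3)
  td <- tidy(basis)
  expect_equal(nrow(td), 8L)
  expect_equal(td$singular_value, basis$singular_values)
  expect_equal(td$cumulative_variance[8], 1, tolerance = 1e-12)
})
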