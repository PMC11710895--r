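# Linear-SVM group prediction over repeated balanced train/test
# subsamplings, with a label-permutation null.
#
# Protocol: 100 random subsamplings into 28 training / 8 testing subjects,
# balanced within group (14+14 / 4+4). Per split, the HOSVD basis is
# refitted on that split's training tensors only, both subsets are
# projected and time-averaged, a linear SVM (cost C = 1, no feature
# scaling) is trained on the training features, and accuracy / sensitivity
# / specificity / cross-entropy are measured on the 8 test subjects.
# Metrics are averaged (mean +/- sd) across the splits, and the per-split
# weight vectors are averaged into an R x R weight matrix. The same split
# scheme is reused verbatim across the sitting-time analysis, the
# step-count analysis, and both permutation nulls. The positive class is
# "low" change; specificity is recall of the "high" (greater improvement)
# class.

#' Balanced repeated train/test split scheme
#'
#' Draws `n_splits` independent splits of the cohort into `n_train`
#' training and `n_test` testing subjects, each balanced within group
#' (`n_train/2` and `n_test/2` subjects per class), uniformly among
#' balanced partitions. Reproducible from `seed`; the same scheme object is
#' meant to be reused across all analyses of a cohort.
#'
#' @param labels A [median_split_groups()] assignment with equal class
#'   sizes.
#' @param n_splits Number of splits (default 100).
#' @param n_train,n_test Training/testing sizes (defaults 28 and 8; both
#'   must be even and sum to the cohort size).
#' @param seed Integer seed.
#' @return An object of class `split_scheme`: list with `splits` (each a
#'   list of `train_ids`, `test_ids`), `seed`, sizes.
#' @export
make_split_scheme <- function(labels, n_splits = 100L, n_train = 28L,
                              n_test = 8L, seed) {
  stopifnot(inherits(labels, "group_assignment"))
  ids <- names(labels$labels)
  low <- sort(ids[labels$labels == "low"])
  high <- sort(ids[labels$labels == "high"])
  n <- length(ids)
  if (length(low) != length(high)) {
    dc_stop("split scheme requires equal class sizes",
            "dynconn_configuration_error")
  }
  if (n_train + n_test != n) {
    dc_stop(sprintf("n_train + n_test must equal the cohort size (%d)", n),
            "dynconn_configuration_error")
  }
  if (n_train %% 2L != 0L || n_test %% 2L != 0L) {
    dc_stop("n_train and n_test must be even (balanced halves)",
            "dynconn_configuration_error")
  }
  k <- n_train / 2L
  if (k > length(low)) {
    dc_stop("classes too small for the requested training size",
            "dynconn_configuration_error")
  }
  splits <- with_seed_local(seed, {
    lapply(seq_len(n_splits), function(s) {
      tr_low <- sample(low, k)
      tr_high <- sample(high, k)
      train <- c(sort(tr_low), sort(tr_high))
      list(train_ids = train, test_ids = sort(setdiff(ids, train)))
    })
  })
  structure(
    list(splits = splits, seed = seed, n_splits = as.integer(n_splits),
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         subject_ids = sort(ids)),
    class = "split_scheme"
  )
}

#' @export
print.split_scheme <- function(x, ...) {
  cat(sprintf("<split_scheme> %d splits of %d train / %d test (seed %d)\n",
              x$n_splits, x$n_train, x$n_test, x$seed))
  invisible(x)
}

# Feature matrix (subjects x p) from a list of reduced_features or a matrix.
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  lens <- vapply(features, function(f) length(f$features), integer(1))
  if (length(unique(lens)) != 1L) {
    dc_stop("all feature vectors must share one length",
            "dynconn_dimension_error")
  }
  X <- t(vapply(features, function(f) f$features, numeric(lens[1])))
  rownames(X) <- vapply(features, function(f) f$subject_id, character(1))
  X
}

#' Train a linear SVM on reduced connectivity features
#'
#' Soft-margin linear SVM (hinge loss, L2 regularization, cost `C`, libsvm
#' backend) with no feature scaling and no hyperparameter tuning. Labels
#' are encoded low -> +1 (positive class), high -> -1; the stored weight
#' vector and bias make `decision(x) = <w, x> + b` with `decision >= 0`
#' predicting "low".
#'
#' @param features List of [time_average_features()] outputs (or a subjects
#'   x p matrix with subject-id rownames).
#' @param labels A [median_split_groups()] assignment covering the
#'   subjects.
#' @param cost Soft-margin cost C (default 1).
#' @return An object of class `linear_svm`: `weights`, `bias`,
#'   `class_map`, `cost`.
#' @export
train_linear_svm <- function(features, labels, cost = 1) {
  X <- feature_matrix(features)
  ids <- rownames(X)
  y <- unname(labels$labels[ids])
  if (anyNA(y)) {
    dc_stop("labels missing for some training subjects",
            "dynconn_validation_error")
  }
  if (length(unique(y)) < 2L) {
    dc_stop("training set contains a single class", "dynconn_training_error")
  }
  yf <- factor(y, levels = c("low", "high"))
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = cost,
                    scale = FALSE, fitted = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's positive decision side is the first label it encountered; read
  # it off the decision-value column name and orient so positive => "low".
  dv <- stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE)
  pos_class <- strsplit(colnames(attr(dv, "decision.values")), "/",
                        fixed = TRUE)[[1L]][1L]
  if (pos_class == "high") {
    w <- -w
    b <- -b
  }
  structure(
    list(weights = unname(w), bias = unname(b),
         class_map = c(positive = "low", negative = "high"), cost = cost),
    class = "linear_svm"
  )
}

#' Decision values of a linear SVM
#' @param object A `linear_svm`.
#' @param features Feature list or matrix.
#' @param ... Unused.
#' @return Named numeric vector of decision values; `>= 0` predicts "low".
#' @export
decision_values <- function(object, features, ...) {
  X <- feature_matrix(features)
  drop(X %*% object$weights) + object$bias
}

#' @export
predict.linear_svm <- function(object, features, ...) {
  dv <- decision_values(object, features)
  stats::setNames(ifelse(dv >= 0, "low", "high"), names(dv))
}

#' Evaluate a trained SVM on one test split
#'
#' Accuracy is the percentage of test subjects classified correctly;
#' sensitivity and specificity are the per-class recalls of the positive
#' ("low") and negative ("high") classes. Cross-entropy is the mean
#' negative log-likelihood in nats under a logistic link on the raw
#' decision values, `p = 1/(1 + exp(-decision))`, with `p` clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param model A [train_linear_svm()] fit.
#' @param test_features Feature list or matrix for the test subjects.
#' @param labels Group assignment covering the test subjects.
#' @param allow_missing_class If TRUE, a test set lacking one class yields
#'   `NA` for that class's recall instead of an error (used by the
#'   permutation null, where whole-cohort relabeling can occasionally
#'   produce a one-class test set).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity` (all in
#'   percent), `cross_entropy` (nats).
#' @export
evaluate_split <- function(model, test_features, labels,
                           allow_missing_class = FALSE) {
  X <- feature_matrix(test_features)
  truth <- unname(labels$labels[rownames(X)])
  if (anyNA(truth)) {
    dc_stop("labels missing for some test subjects",
            "dynconn_validation_error")
  }
  if (!allow_missing_class && length(unique(truth)) < 2L) {
    dc_stop("a class is absent from the test set", "dynconn_evaluation_error")
  }
  dv <- drop(X %*% model$weights) + model$bias
  pred <- ifelse(dv >= 0, "low", "high")
  recall <- function(class) {
    idx <- truth == class
    if (!any(idx)) return(NA_real_)
    100 * mean(pred[idx] == class)
  }
  p <- pmin(pmax(stats::plogis(dv), 1e-12), 1 - 1e-12)
  y <- as.numeric(truth == "low")
  tibble::tibble(
    accuracy = 100 * mean(pred == truth),
    sensitivity = recall("low"),
    specificity = recall("high"),
    cross_entropy = -mean(y * log(p) + (1 - y) * log(1 - p)))
}

#' Average per-split SVM weight vectors into a weight matrix
#'
#' Entrywise mean of the length-`rank^2` weight vectors, unflattened
#' row-major to `rank x rank` (17 x 17 at the study rank). Diagonal entries
#' weight single-component features; off-diagonal entries weight component
#' interactions.
#'
#' @param weight_vectors List (or matrix with one row per split) of weight
#'   vectors, all of length `rank^2`.
#' @param rank Component rank R.
#' @return An object of class `weight_matrix_summary`: `matrix` (R x R),
#'   `n_splits`.
#' @export
summarize_weight_matrix <- function(weight_vectors, rank) {
  if (is.list(weight_vectors)) {
    lens <- lengths(weight_vectors)
    if (any(lens != rank^2)) {
      dc_stop(sprintf("all weight vectors must have length rank^2 = %d",
                      rank^2), "dynconn_dimension_error")
    }
    Wm <- do.call(rbind, weight_vectors)
  } else {
    Wm <- as.matrix(weight_vectors)
    if (ncol(Wm) != rank^2) {
      dc_stop(sprintf("weight vectors must have length rank^2 = %d", rank^2),
              "dynconn_dimension_error")
    }
  }
  structure(
    list(matrix = matrix(colMeans(Wm), nrow = rank, ncol = rank, byrow = TRUE),
         n_splits = nrow(Wm)),
    class = "weight_matrix_summary"
  )
}

#' @export
print.weight_matrix_summary <- function(x, ...) {
  cat(sprintf("<weight_matrix_summary> %d x %d, averaged over %d splits\n",
              nrow(x$matrix), ncol(x$matrix), x$n_splits))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CV engine shared by run_repeated_cv and run_permutation_null.
#
# labels_per_split: list of length n_splits of named label vectors
# (subject_id -> "low"/"high"); for the standard analysis every element is
# the observed labels.
run_cv_engine <- function(tensors, labels_per_split, scheme,
                          variance_threshold = 0.85, rank = NULL, cost = 1,
                          allow_missing_class = FALSE) {
  stopifnot(inherits(scheme, "split_scheme"))
  all_ids <- unique(unlist(lapply(scheme$splits,
                                  function(s) c(s$train_ids, s$test_ids))))
  missing <- setdiff(all_ids, names(tensors))
  if (length(missing) > 0L) {
    dc_stop(paste0("missing dynamic tensors for subject(s): ",
                   paste(missing, collapse = ", ")),
            "dynconn_validation_error")
  }
  N <- dim(tensors[[1L]]$data)[1L]
  # Per-subject sufficient statistics. The training Gram of a split is the
  # sum of its members' Grams; the time-averaged reduced slice of a subject
  # is U' Cbar U (exactly the time average of the projected slices, by
  # linearity).
  grams <- lapply(tensors, tensor_gram)
  means <- lapply(tensors, tensor_mean_slice)

  n_splits <- scheme$n_splits
  split_eigs <- vector("list", n_splits)
  split_ranks <- integer(n_splits)
  for (s in seq_len(n_splits)) {
    tr <- scheme$splits[[s]]$train_ids
    G <- Reduce(`+`, grams[tr])
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    sv <- sqrt(pmax(eg$values, 0))
    split_eigs[[s]] <- list(U = fix_column_signs(eg$vectors), sv = sv)
    split_ranks[s] <- select_rank(sv, variance_threshold)
  }
  # One feature length across splits: a fixed rank when given, otherwise the
  # maximum of the per-split minimal ranks.
  R <- if (is.null(rank)) max(split_ranks) else as.integer(rank)
  if (R > N) {
    dc_stop(sprintf("rank %d exceeds the number of regions %d", R, N),
            "dynconn_range_error")
  }

  per_split <- vector("list", n_splits)
  weight_vectors <- vector("list", n_splits)
  bases <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- scheme$splits[[s]]
    U <- split_eigs[[s]]$U[, seq_len(R), drop = FALSE]
    bases[[s]] <- structure(
      list(basis = U, singular_values = split_eigs[[s]]$sv,
           variance_fractions = cumsum(split_eigs[[s]]$sv^2) /
             sum(split_eigs[[s]]$sv^2),
           rank = R, variance_threshold = variance_threshold,
           training_ids = sp$train_ids),
      class = "connectivity_basis")
    feat <- function(ids) {
      X <- t(vapply(ids, function(id) {
        as.vector(t(crossprod(U, means[[id]]) %*% U))
      }, numeric(R * R)))
      rownames(X) <- ids
      X
    }
    lab <- structure(list(measure = "split", labels = labels_per_split[[s]],
                          median_value = NA_real_, improvement_sign = NA),
                     class = "group_assignment")
    model <- train_linear_svm(feat(sp$train_ids), lab, cost = cost)
    metrics <- evaluate_split(model, feat(sp$test_ids), lab,
                              allow_missing_class = allow_missing_class)
    weight_vectors[[s]] <- model$weights
    per_split[[s]] <- tibble::tibble(split = s, metrics,
                                     minimal_rank = split_ranks[s])
  }
  per_split <- do.call(rbind, per_split)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "cross_entropy")
  aggregate <- tibble::as_tibble(c(
    stats::setNames(lapply(metric_cols, function(m)
      mean(per_split[[m]], na.rm = TRUE)), paste0(metric_cols, "_mean")),
    stats::setNames(lapply(metric_cols, function(m)
      stats::sd(per_split[[m]], na.rm = TRUE)), paste0(metric_cols, "_sd"))))
  structure(
    list(per_split = per_split,
         aggregate = aggregate,
         weight_matrix = summarize_weight_matrix(weight_vectors, R),
         weight_vectors = weight_vectors,
         bases = bases,
         rank = R,
         per_split_ranks = split_ranks,
         scheme = scheme,
         config = list(variance_threshold = variance_threshold,
                       rank = rank, cost = cost)),
    class = "repeated_cv_result"
  )
}

#' Repeated-subsampling cross-validated prediction
#'
#' Runs the full per-split pipeline over every split of `scheme`: fit the
#' HOSVD basis on that split's training tensors only, project and
#' time-average both subsets, train a linear SVM, and evaluate on the test
#' subjects. No quantity fitted in a split depends on that split's test
#' subjects. When `rank` is `NULL` the run-level rank is the maximum of the
#' per-split minimal ranks (so the feature length — and hence the averaged
#' weight matrix — is constant across splits); a fixed `rank` (the study
#' uses 17) overrides this.
#'
#' @param tensors Named list (by subject id) of [build_dynamic_networks()]
#'   outputs covering the cohort.
#' @param labels A [median_split_groups()] assignment.
#' @param scheme A [make_split_scheme()] scheme.
#' @param variance_threshold HOSVD variance criterion (default 0.85).
#' @param rank Optional fixed rank.
#' @param cost SVM cost (default 1).
#' @return An object of class `repeated_cv_result`: `per_split` metrics
#'   tibble, `aggregate` (mean/sd per metric), `weight_matrix`, the
#'   per-split `weight_vectors` and `bases`, `rank`, `scheme`, `config`.
#' @export
run_repeated_cv <- function(tensors, labels, scheme,
                            variance_threshold = 0.85, rank = NULL,
                            cost = 1) {
  stopifnot(inherits(labels, "group_assignment"))
  labels_per_split <- rep(list(labels$labels), scheme$n_splits)
  res <- run_cv_engine(tensors, labels_per_split, scheme,
                       variance_threshold = variance_threshold, rank = rank,
                       cost = cost, allow_missing_class = FALSE)
  res$measure <- labels$measure
  res$null <- FALSE
  res
}

#' Label-permutation null of the repeated-CV analysis
#'
#' Re-runs the identical per-split pipeline (same split scheme) after
#' permuting the group labels of the entire cohort. By default one balanced
#' relabeling (preserving the low/high counts) is drawn independently per
#' split (`permute = "per_split"`); `permute = "once"` draws a single
#' relabeling for the whole run. Mean accuracy estimates the chance level
#' (the study observed 49.59% for sitting time and 50.09% for step count).
#'
#' @inheritParams run_repeated_cv
#' @param seed Integer seed for the relabelings (independent of the
#'   scheme's seed).
#' @param permute `"per_split"` (default) or `"once"`.
#' @return A `repeated_cv_result` with `null = TRUE`.
#' @export
run_permutation_null <- function(tensors, labels, scheme, seed,
                                 variance_threshold = 0.85, rank = NULL,
                                 cost = 1, permute = c("per_split", "once")) {
  stopifnot(inherits(labels, "group_assignment"))
  permute <- match.arg(permute)
  ids <- names(labels$labels)
  n_low <- sum(labels$labels == "low")
  draw <- function() {
    low_ids <- sample(ids, n_low)
    stats::setNames(ifelse(ids %in% low_ids, "low", "high"), ids)
  }
  labels_per_split <- with_seed_local(seed, {
    if (permute == "per_split") {
      lapply(seq_len(scheme$n_splits), function(s) draw())
    } else {
      rep(list(draw()), scheme$n_splits)
    }
  })
  res <- run_cv_engine(tensors, labels_per_split, scheme,
                       variance_threshold = variance_threshold, rank = rank,
                       cost = cost, allow_missing_class = TRUE)
  res$measure <- labels$measure
  res$null <- TRUE
  res$null_seed <- seed
  res$null_permute <- permute
  res
}

#' @export
print.repeated_cv_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<repeated_cv_result>%s %d splits, rank %d\n  accuracy %.2f +/- %.2f %%  sensitivity %.2f  specificity %.2f  cross-entropy %.4f\n",
    if (isTRUE(x$null)) " [permutation null]" else "",
    nrow(x$per_split), x$rank,
    a$accuracy_mean, a$accuracy_sd, a$sensitivity_mean, a$specificity_mean,
    a$cross_entropy_mean))
  invisible(x)
}

#' Tidy per-split CV metrics
#' @param x A `repeated_cv_result`.
#' @param ... Unused.
#' @return The per-split metrics tibble.
#' @method tidy repeated_cv_result
#' @export
tidy.repeated_cv_result <- function(x, ...) x$per_split

#' One-row summary of a repeated-CV result
#' @param x A `repeated_cv_result`.
#' @param ... Unused.
#' @return One-row tibble of aggregate metrics plus `rank` and `n_splits`.
#' @method glance repeated_cv_result
#' @export
glance.repeated_cv_result <- function(x, ...) {
  tibble::tibble(x$aggregate, rank = x$rank, n_splits = nrow(x$per_split),
                 null = isTRUE(x$null))
}
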