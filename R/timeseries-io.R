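# Reading/validating ROI time series, atlas metadata, cohort manifests, and
# writing result artifacts.
#
# File conventions:
#   * time series: UTF-8 TSV, rows = time points (TRs), columns = regions in
#     atlas order, optional single header row (auto-detected);
#   * atlas: CSV with header region_id,label,x,y,z,subnetwork;
#   * manifest: CSV with header
#     subject_id,timeseries_path,st_baseline,st_6mo,ns_baseline,ns_6mo.

#' Construct a subject time-series object
#'
#' Wraps a numeric time-by-region matrix of BOLD-like ROI signals with its
#' subject id and repetition time, validating the invariants every pipeline
#' stage relies on: a fully finite matrix with at least 2 time points and 2
#' regions.
#'
#' @param data Numeric matrix, time points (rows) by regions (columns).
#' @param subject_id Character scalar identifying the subject.
#' @param tr_seconds Repetition time in seconds (sampling interval of the
#'   fMRI volumes); the study protocol uses 2.0.
#'
#' @return An object of class `subject_timeseries`.
#' @export
subject_timeseries <- function(data, subject_id, tr_seconds = 2) {
  if (!is.matrix(data) || !is.numeric(data)) {
    dc_stop("`data` must be a numeric matrix (time x regions)",
            "dynconn_validation_error")
  }
  if (nrow(data) < 2L || ncol(data) < 2L) {
    dc_stop(sprintf(
      "time series must have >= 2 time points and >= 2 regions (got %d x %d)",
      nrow(data), ncol(data)), "dynconn_dimension_error")
  }
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    dc_stop(sprintf("non-finite value at time point %d, region %d",
                    bad[1L], bad[2L]), "dynconn_validation_error")
  }
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    dc_stop("`subject_id` must be a single string", "dynconn_validation_error")
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    dc_stop("`tr_seconds` must be a positive number", "dynconn_validation_error")
  }
  dimnames(data) <- NULL
  structure(
    list(subject_id = subject_id, data = data, tr_seconds = as.numeric(tr_seconds)),
    class = "subject_timeseries"
  )
}

#' @export
print.subject_timeseries <- function(x, ...) {
  cat(sprintf("<subject_timeseries> %s: %d time points x %d regions, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Number of time points / regions of a subject time series
#' @param ts A `subject_timeseries`.
#' @return Integer scalar.
#' @export
n_timepoints <- function(ts) nrow(ts$data)

#' @rdname n_timepoints
#' @export
n_regions <- function(ts) ncol(ts$data)

# Parse one TSV line into tokens.
split_tsv_line <- function(line) strsplit(line, "\t", fixed = TRUE)[[1L]]

#' Read a subject ROI time series from TSV
#'
#' Reads a tab-delimited matrix with rows = time points and columns = regions
#' (atlas order). A single header row is tolerated and auto-detected: if any
#' token of the first row fails to parse as a number it is treated as a
#' header. Scientific notation is accepted. Any non-numeric cell or
#' non-finite value is an error that names the offending row and column.
#'
#' @param path Path to the TSV file.
#' @param expected_regions If given, the column count must equal it.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param tr_seconds Repetition time in seconds (default 2).
#'
#' @return A [subject_timeseries()] object.
#' @export
read_subject_timeseries <- function(path, expected_regions = NULL,
                                    subject_id = NULL, tr_seconds = 2) {
  if (!file.exists(path)) {
    dc_stop(sprintf("time-series file not found: %s", path), "dynconn_io_error")
  }
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    dc_stop(sprintf("empty time-series file: %s", path), "dynconn_io_error")
  }
  first <- split_tsv_line(lines[[1L]])
  first_num <- suppressWarnings(as.numeric(first))
  has_header <- anyNA(first_num) && !all(toupper(trimws(first)) %in% c("NA", "NAN"))
  body <- if (has_header) lines[-1L] else lines
  row_offset <- if (has_header) 1L else 0L
  tokens <- lapply(body, split_tsv_line)
  ncols <- lengths(tokens)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    dc_stop(sprintf("ragged TSV: row %d has %d columns, expected %d",
                    bad + row_offset, ncols[bad], ncols[1L]),
            "dynconn_parse_error")
  }
  n_col <- ncols[1L]
  mat <- matrix(NA_real_, nrow = length(body), ncol = n_col)
  for (r in seq_along(tokens)) {
    v <- suppressWarnings(as.numeric(tokens[[r]]))
    if (anyNA(v)) {
      literal_na <- toupper(trimws(tokens[[r]])) %in% c("NA", "NAN")
      bad <- which(is.na(v) & !literal_na)
      if (length(bad) > 0L) {
        dc_stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                        tokens[[r]][bad[1L]], r + row_offset, bad[1L]),
                "dynconn_parse_error")
      }
    }
    mat[r, ] <- v
  }
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    dc_stop(sprintf("missing/non-finite value at row %d, column %d of %s",
                    bad[1L] + row_offset, bad[2L], path),
            "dynconn_validation_error")
  }
  if (!is.null(expected_regions) && n_col != expected_regions) {
    dc_stop(sprintf("expected %d regions but %s has %d columns",
                    expected_regions, path, n_col), "dynconn_dimension_error")
  }
  subject_timeseries(mat, subject_id = subject_id, tr_seconds = tr_seconds)
}

#' Write a subject time series to TSV
#'
#' Values are written in decimal/`%g` notation with `digits` significant
#' digits (default 15) so that a write/read round trip reproduces values
#' representable at that precision exactly. No header row is written.
#'
#' @param ts A [subject_timeseries()].
#' @param path Output path.
#' @param digits Significant digits to write (>= 10).
#' @return `path`, invisibly.
#' @export
write_subject_timeseries <- function(ts, path, digits = 15) {
  stopifnot(inherits(ts, "subject_timeseries"))
  if (digits < 10) dc_stop("`digits` must be >= 10", "dynconn_validation_error")
  fmt <- paste0("%.", digits, "g")
  lines <- apply(ts$data, 1L, function(row) paste(sprintf(fmt, row), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read atlas region metadata
#'
#' Reads a CSV with columns `region_id,label,x,y,z,subnetwork` describing the
#' parcellation (e.g., the 268-region Shen atlas): MNI coordinates in mm and
#' the assignment of every region to exactly one of the eight canonical
#' subnetworks ([SUBNETWORKS]).
#'
#' @param path Path to the atlas CSV.
#' @param n_regions Expected number of regions; `region_id` must be a
#'   permutation of `1:n_regions`.
#'
#' @return A tibble with columns `region_id`, `label`, `x`, `y`, `z`,
#'   `subnetwork`, sorted by `region_id`.
#' @export
read_atlas_info <- function(path, n_regions) {
  if (!file.exists(path)) {
    dc_stop(sprintf("atlas file not found: %s", path), "dynconn_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "label", "x", "y", "z", "subnetwork")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    dc_stop(paste0("atlas CSV is missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "dynconn_parse_error")
  }
  df <- df[need]
  if (!setequal(df$region_id, seq_len(n_regions)) ||
      nrow(df) != n_regions) {
    dc_stop(sprintf(
      "atlas region_id must be a permutation of 1..%d (got %d rows)",
      n_regions, nrow(df)), "dynconn_completeness_error")
  }
  bad <- setdiff(unique(df$subnetwork), SUBNETWORKS)
  if (length(bad) > 0L) {
    dc_stop(paste0("unknown subnetwork code(s): ", paste(bad, collapse = ", "),
                   "; expected one of ", paste(SUBNETWORKS, collapse = ", ")),
            "dynconn_validation_error")
  }
  df <- df[order(df$region_id), ]
  tibble::as_tibble(df)
}

#' Write atlas region metadata
#' @param atlas Tibble as returned by [read_atlas_info()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_atlas_info <- function(atlas, path) {
  utils::write.csv(atlas, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest lists one subject per row: the subject id, the path of its
#' ROI time-series TSV (resolved relative to the manifest's directory when
#' not absolute), and the four behavioral summaries — baseline and 6-month
#' daily sitting time (min/day) and daily step count (steps/day).
#'
#' @param path Path to the manifest CSV.
#' @param check_paths Verify that every time-series path resolves to an
#'   existing file (default TRUE).
#'
#' @return A tibble with columns `subject_id`, `timeseries_path`,
#'   `st_baseline`, `st_6mo`, `ns_baseline`, `ns_6mo`.
#' @export
read_cohort_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) {
    dc_stop(sprintf("manifest not found: %s", path), "dynconn_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timeseries_path", "st_baseline", "st_6mo",
            "ns_baseline", "ns_6mo")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    dc_stop(paste0("manifest is missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "dynconn_parse_error")
  }
  df <- df[need]
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0L) {
    dc_stop(paste0("duplicate subject_id in manifest: ",
                   paste(unique(dup), collapse = ", ")),
            "dynconn_uniqueness_error")
  }
  beh <- c("st_baseline", "st_6mo", "ns_baseline", "ns_6mo")
  for (col in beh) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      dc_stop(sprintf("manifest column %s must be finite numeric", col),
              "dynconn_validation_error")
    }
    if (any(v < 0)) {
      dc_stop(sprintf("negative behavioral value in column %s (subject %s)",
                      col, df$subject_id[which(v < 0)[1L]]),
              "dynconn_validation_error")
    }
  }
  base_dir <- dirname(path)
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }
  df$timeseries_path <- resolve(df$timeseries_path)
  if (check_paths) {
    missing_ts <- !file.exists(df$timeseries_path)
    if (any(missing_ts)) {
      dc_stop(sprintf("time-series file not found for subject %s: %s",
                      df$subject_id[which(missing_ts)[1L]],
                      df$timeseries_path[which(missing_ts)[1L]]),
              "dynconn_io_error")
    }
  }
  tibble::as_tibble(df)
}

#' Write aggregate prediction metrics to JSON
#'
#' @param metrics A named list or one-row data frame of metric values (e.g.,
#'   from [glance.repeated_cv_result()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a component edge list to TSV
#'
#' One retained edge per row: `region_i`, `region_j`, `weight` — the
#' node/edge convention of standard brain-network viewers.
#'
#' @param map A thresholded `component_map` (see
#'   [threshold_component_edges()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(map, path) {
  stopifnot(inherits(map, "component_map"))
  if (is.null(map$top_edges)) {
    dc_stop("component map has no thresholded edges; run threshold_component_edges() first",
            "dynconn_validation_error")
  }
  utils::write.table(map$top_edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a component node table to TSV
#'
#' One region per row: `region_id`, `label`, `subnetwork`, `degree` (the
#' number of retained edges incident to the region in the thresholded
#' component map).
#'
#' @param map A thresholded `component_map`.
#' @param atlas Atlas tibble from [read_atlas_info()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(map, atlas, path) {
  stopifnot(inherits(map, "component_map"))
  if (is.null(map$node_degrees)) {
    dc_stop("component map has no node degrees; run threshold_component_edges() first",
            "dynconn_validation_error")
  }
  if (nrow(atlas) != length(map$node_degrees)) {
    dc_stop("atlas size does not match component map", "dynconn_dimension_error")
  }
  out <- data.frame(region_id = atlas$region_id, label = atlas$label,
                    subnetwork = atlas$subnetwork,
                    degree = map$node_degrees[atlas$region_id])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
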