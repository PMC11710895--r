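# Pre-post behavioral change scores and the median-split group labels.
#
# The two outcomes are daily sitting time (st, min/day) and daily step count
# (ns, steps/day); the change score is 6-month value minus baseline, and each
# cohort is dichotomized at the median of its change scores into low- and
# high-change groups. "High" means greater *improvement*: for sitting time
# improvement is a decrease (improvement_sign = -1), for steps an increase
# (improvement_sign = +1).

#' Pre-post change score
#'
#' `change = month6 - baseline`, the quantity the median split and all group
#' labels are built on. Vectorized.
#'
#' @param baseline,month6 Finite numeric values (min/day for sitting time,
#'   steps/day for step count).
#' @return `month6 - baseline`.
#' @examples
#' compute_change(535.48, 598.61)  #  63.13
#' compute_change(7172.6, 6463.4)  # -709.2
#' @export
compute_change <- function(baseline, month6) {
  if (!is.numeric(baseline) || !is.numeric(month6) ||
      any(!is.finite(baseline)) || any(!is.finite(month6))) {
    dc_stop("baseline and month6 must be finite numeric",
            "dynconn_validation_error")
  }
  month6 - baseline
}

#' Default improvement sign for a behavioral measure
#'
#' @param measure `"st"` (sitting time; improvement = decrease, sign -1) or
#'   `"ns"` (step count; improvement = increase, sign +1).
#' @return `-1` or `+1`.
#' @export
default_improvement_sign <- function(measure = c("st", "ns")) {
  measure <- match.arg(measure)
  if (measure == "st") -1 else +1
}

#' Extract behavior records from a cohort manifest
#'
#' @param manifest Tibble from [read_cohort_manifest()] (columns
#'   `subject_id`, `st_baseline`, `st_6mo`, `ns_baseline`, `ns_6mo`).
#' @param measure `"st"` or `"ns"`.
#' @return Tibble with columns `subject_id`, `measure`, `baseline`,
#'   `month6`, `change`.
#' @export
behavior_records <- function(manifest, measure = c("st", "ns")) {
  measure <- match.arg(measure)
  base_col <- paste0(measure, "_baseline")
  m6_col <- paste0(measure, "_6mo")
  if (!all(c("subject_id", base_col, m6_col) %in% names(manifest))) {
    dc_stop("manifest lacks the required behavioral columns",
            "dynconn_validation_error")
  }
  tibble::tibble(
    subject_id = as.character(manifest$subject_id),
    measure = measure,
    baseline = manifest[[base_col]],
    month6 = manifest[[m6_col]],
    change = compute_change(manifest[[base_col]], manifest[[m6_col]])
  )
}

#' Median-split group assignment
#'
#' Ranks subjects by the improvement score `s_i = improvement_sign *
#' change_i` and labels those strictly above the cohort median of `s` as
#' "high" (greater improvement) and those strictly below as "low". Subjects
#' exactly at the median are first assigned to "low", then moved to "high"
#' in ascending `subject_id` order until the split is balanced (exactly
#' balanced for even cohorts, within one for odd). The median is the
#' midpoint of the two central order statistics for even n.
#'
#' @param records Tibble from [behavior_records()]: >= 2 rows, one measure.
#' @param improvement_sign `+1` or `-1`; defaults to the measure's
#'   convention via [default_improvement_sign()].
#' @return An object of class `group_assignment`: list with `measure`,
#'   `labels` (named character vector, subject_id -> "low"/"high"),
#'   `median_value` (median of the raw change scores), `improvement_sign`.
#' @export
median_split_groups <- function(records, improvement_sign = NULL) {
  if (nrow(records) < 2L) {
    dc_stop("need at least 2 behavior records for a median split",
            "dynconn_size_error")
  }
  measure <- unique(records$measure)
  if (length(measure) != 1L) {
    dc_stop("all records must share one measure", "dynconn_validation_error")
  }
  improvement_sign <- improvement_sign %||% default_improvement_sign(measure)
  if (!improvement_sign %in% c(-1, 1)) {
    dc_stop("improvement_sign must be +1 or -1", "dynconn_validation_error")
  }
  ids <- records$subject_id
  if (anyDuplicated(ids)) {
    dc_stop("duplicate subject_id in behavior records",
            "dynconn_uniqueness_error")
  }
  s <- improvement_sign * records$change
  med_s <- stats::median(s)
  lab <- ifelse(s > med_s, "high", "low")  # ties -> "low" first
  tie <- s == med_s
  n <- length(s)
  even <- n %% 2L == 0L
  balanced <- function(l) {
    d <- sum(l == "low") - sum(l == "high")
    if (even) d == 0L else abs(d) <= 1L
  }
  tie_order <- order(ids)[tie[order(ids)]]  # tied subjects, ascending id
  k <- 1L
  while (!balanced(lab)) {
    if (k > length(tie_order)) {
      dc_stop("cannot balance median split (internal invariant violated)",
              "dynconn_validation_error")
    }
    lab[tie_order[k]] <- "high"
    k <- k + 1L
  }
  labels <- stats::setNames(lab, ids)
  structure(
    list(measure = measure,
         labels = labels,
         median_value = stats::median(records$change),
         improvement_sign = improvement_sign),
    class = "group_assignment"
  )
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf(
    "<group_assignment> measure=%s: %d low / %d high (median change %.4g, improvement sign %+d)\n",
    x$measure, sum(x$labels == "low"), sum(x$labels == "high"),
    x$median_value, x$improvement_sign))
  invisible(x)
}

#' Tidy a group assignment into a tibble
#' @param x A `group_assignment`.
#' @param ... Unused.
#' @return Tibble with columns `subject_id`, `measure`, `group`.
#' @method tidy group_assignment
#' @export
tidy.group_assignment <- function(x, ...) {
  tibble::tibble(subject_id = names(x$labels), measure = x$measure,
                 group = unname(x$labels))
}

#' Write a groups table to TSV
#'
#' Emits `subject_id`, `measure`, `change`, `group` for downstream record
#' keeping.
#'
#' @param assignment A `group_assignment`.
#' @param records The behavior records the assignment was computed from.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(assignment, records, path) {
  out <- data.frame(subject_id = records$subject_id,
                    measure = records$measure,
                    change = records$change,
                    group = unname(assignment$labels[records$subject_id]))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
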