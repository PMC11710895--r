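# Internal helpers shared across modules.

#' @importFrom stats median sd cor fft mvfft quantile rnorm runif plogis
#' @importFrom utils read.csv write.csv head
NULL

# Run code with a locally seeded RNG, restoring the caller's stream afterwards.
with_seed_local <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# round() uses banker's rounding; edge counts need half-away-from-zero.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

n_undirected_edges <- function(n_regions) {
  n_regions * (n_regions - 1) / 2
}

# Upper-triangle (i < j) index pairs in row-major order (ascending i, then j).
upper_tri_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

dc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dynconn_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    dc_stop(sprintf("%s must be a square matrix", what), "dynconn_dimension_error")
  }
  if (max(abs(m - t(m))) > tol) {
    dc_stop(sprintf("%s must be symmetric", what), "dynconn_validation_error")
  }
  invisible(TRUE)
}

#' The eight canonical brain subnetworks
#'
#' Codes used to label atlas regions: default mode (DMN), central executive
#' (CEN), dorsal attention (DAN), sensorimotor (SMN), salience (SAL), basal
#' ganglia (BGN), visual (VIS), and frontotemporal (FTN).
#'
#' @format Character vector of length 8.
#' @export
SUBNETWORKS <- c("DMN", "CEN", "DAN", "SMN", "SAL", "BGN", "VIS", "FTN")
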