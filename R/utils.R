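#' @importFrom rlang abort %||% .data
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   left_join bind_rows n across all_of pull rename distinct
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 imap
#' @importFrom stats rnorm runif rbinom pnorm qnorm sd var binom.test
#'   prop.test pf predict complete.cases plogis qlogis setNames
NULL

# Deterministic substream seeding: one user-facing seed fans out to
# independent per-subject / per-stage seeds. Keyed mixing keeps substreams
# stable when cohort size or stage order changes. All arithmetic stays below
# 2^53 so the double-precision modular reduction is exact; results fit in a
# 32-bit R integer.
substream_seed <- function(seed, ...) {
  keys <- c(...)
  x <- (as.double(seed) %% 2147483647) + 1
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    x <- (x * 69069 + (as.double(k) %% 2147483647) * 40503 + 12345) %% 2147483629
  }
  as.integer(x %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1].", name),
          class = "cc_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "cc_config_error")
  }
  invisible(as.integer(x))
}

# Validate a weighted connectivity matrix: square, symmetric (within tol),
# finite off-diagonal; returns the matrix with the diagonal zeroed.
check_connectivity_matrix <- function(w, tol = 1e-9) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    abort("Connectivity matrix must be square.", class = "cc_matrix_error")
  }
  if (max(abs(w - t(w))) > tol) {
    abort("Connectivity matrix must be symmetric.", class = "cc_matrix_error")
  }
  diag(w) <- 0
  if (any(!is.finite(w))) {
    abort("Connectivity matrix contains non-finite values.",
          class = "cc_matrix_error")
  }
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- paste0("R", seq_len(nrow(w)))
  }
  w
}
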