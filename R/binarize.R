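#' Binarize a weighted connectivity matrix to minimum connection density
#'
#' Edges are admitted in descending absolute-weight order until every region
#' is reachable from every other (no fragmented node); the resulting edge
#' fraction is the network's minimum connection density. Edges whose absolute
#' weight ties the last admitted edge are admitted with it, so a matrix that
#' is already binary and connected is returned unchanged at its own density.
#' Zero weights never count as candidate edges.
#'
#' @param w Symmetric numeric matrix with zero diagonal (region labels as
#'   dimnames; generated if absent).
#' @param density Optional fixed density in (0, 1]. When supplied, the top
#'   `round(density * n(n-1)/2)` edges are admitted instead of searching for
#'   the connectivity minimum; ties at the cutoff are broken by (lower row
#'   index, lower column index).
#' @return An object of class `cc_binary_network`: list with `adjacency`
#'   (0/1 matrix), `density`, `n_edges` and `region_labels`.
#' @export
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 0.9
#' w[2, 3] <- w[3, 2] <- 0.5
#' w[1, 3] <- w[3, 1] <- 0.1
#' binarize_min_density(w)$density  # 2/3
binarize_min_density <- function(w, density = NULL) {
  w <- check_connectivity_matrix(w)
  n <- nrow(w)
  labs <- rownames(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  aw <- abs(w[ut])
  keep <- aw > 0
  ut <- ut[keep, , drop = FALSE]
  aw <- aw[keep]
  ord <- order(-aw, ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  aw <- aw[ord]
  n_pairs <- n * (n - 1) / 2

  if (!is.null(density)) {
    m <- round(density * n_pairs)
    if (m < 0 || m > nrow(ut)) {
      abort("Requested density admits more edges than the matrix has nonzero weights.",
            class = "cc_density_error")
    }
  } else {
    if (!connected_at(ut, nrow(ut), n)) {
      abort("Matrix cannot be binarized: even with all nonzero edges the network is fragmented.",
            class = "cc_density_error")
    }
    lo <- n - 1
    hi <- nrow(ut)
    while (lo < hi) { # connectivity is monotone in admitted-edge count
      mid <- (lo + hi) %/% 2
      if (connected_at(ut, mid, n)) hi <- mid else lo <- mid + 1
    }
    m <- hi
    # admit the full tie group of the cutoff weight
    while (m < nrow(ut) && aw[m + 1] == aw[m]) m <- m + 1
  }

  adj <- matrix(0L, n, n, dimnames = list(labs, labs))
  if (m > 0) {
    sel <- ut[seq_len(m), , drop = FALSE]
    adj[sel] <- 1L
    adj[sel[, c(2, 1), drop = FALSE]] <- 1L
  }
  structure(
    list(adjacency = adj, density = m / n_pairs, n_edges = m,
         region_labels = labs),
    class = "cc_binary_network"
  )
}

connected_at <- function(ut, m, n) {
  if (m < n - 1) return(FALSE)
  g <- igraph::graph_from_edgelist(ut[seq_len(m), , drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n) return(FALSE)
  igraph::components(g)$no == 1
}

#' @export
print.cc_binary_network <- function(x, ...) {
  cat(sprintf("<cc_binary_network> %d regions, %d edges, density %.4f\n",
              length(x$region_labels), x$n_edges, x$density))
  invisible(x)
}

#' Binarize a cohort of connectivity matrices at a shared or per-subject density
#'
#' `cohort_common` (the default) computes every subject's minimum connection
#' density and applies the maximum of those minima to all subjects, so the
#' whole cohort is analysed at one density and every network stays connected.
#' `per_subject` keeps each subject at its own minimum.
#'
#' @param matrices Named list of symmetric weighted matrices (one per subject).
#' @param mode `"cohort_common"` or `"per_subject"`.
#' @param density_reference_ids Optional subject ids whose minimum densities
#'   define the common density (e.g. training subjects only, to keep held-out
#'   subjects out of density selection). Default: all subjects.
#' @return Named list of [binarize_min_density()] networks, with attributes
#'   `density` (the applied common density, `cohort_common` only) and
#'   `density_reference_ids`.
#' @export
binarize_cohort <- function(matrices,
                            mode = c("cohort_common", "per_subject"),
                            density_reference_ids = NULL) {
  mode <- match.arg(mode)
  if (length(matrices) == 0) {
    abort("`matrices` is empty.", class = "cc_config_error")
  }
  if (is.null(names(matrices))) names(matrices) <- seq_along(matrices)
  own <- map(matrices, binarize_min_density)
  if (mode == "per_subject") {
    return(structure(own, density_reference_ids = names(matrices)))
  }
  ref <- density_reference_ids %||% names(matrices)
  missing_ref <- setdiff(ref, names(matrices))
  if (length(missing_ref) > 0) {
    abort(paste0("Unknown density reference subjects: ",
                 paste(missing_ref, collapse = ", ")),
          class = "cc_config_error")
  }
  d_common <- max(map_dbl(own[ref], "density"))
  nets <- map(matrices, binarize_min_density, density = d_common)
  structure(nets, density = d_common, density_reference_ids = ref)
}
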