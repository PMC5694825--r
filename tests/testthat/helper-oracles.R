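# Brute-force graph-metric oracles, independent of the package (and of
# igraph): direct enumeration over neighbor pairs and BFS path counting.

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- 0
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        t_i <- t_i + adj[nb[a], nb[b]]
      }
    }
    2 * t_i / (k * (k - 1))
  }, numeric(1))
}

# Unnormalized betweenness: BFS from every node gives distances and
# shortest-path counts; a node v lies on an s-t geodesic iff
# d(s,v) + d(v,t) = d(s,t), contributing sigma_sv * sigma_vt / sigma_st.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs <- function(s) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    dist[s] <- 0
    sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(seq_len(n), bfs)
  bw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (is.infinite(sp[[s]]$dist[t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t || is.infinite(sp[[s]]$dist[v])) next
        if (sp[[s]]$dist[v] + sp[[t]]$dist[v] == sp[[s]]$dist[t]) {
          bw[v] <- bw[v] +
            sp[[s]]$sigma[v] * sp[[t]]$sigma[v] / sp[[s]]$sigma[t]
        }
      }
    }
  }
  bw
}

random_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    ut <- upper.tri(a)
    a[ut] <- rbinom(sum(ut), 1, p)
    a + t(a)
  })
}

random_weights <- function(n, seed) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    w[ut] <- runif(sum(ut), -1, 1)
    w + t(w)
  })
}

adjacency_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (i in seq_len(nrow(edges))) {
    a[edges[i, 1], edges[i, 2]] <- 1
    a[edges[i, 2], edges[i, 1]] <- 1
  }
  a
}

# Long cognition tibble with a fixed control reference (mean 10, sd 2,
# higher-better tests) plus patient rows at given z-deviations.
cognition_panel <- function(patient_z, n_controls = 20, seed = 42,
                            timepoints = c("baseline", "year1")) {
  tests <- paste0("T", seq_len(5))
  rows <- list()
  withr::with_seed(seed, {
    for (i in seq_len(n_controls)) {
      for (tp in timepoints) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sprintf("c%02d", i), group = "control",
          timepoint = tp, test = tests, raw_score = rnorm(5, 10, 2))
      }
    }
  })
  for (id in names(patient_z)) {
    for (tp in timepoints) {
      z <- patient_z[[id]][[tp]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = id, group = "patient", timepoint = tp, test = tests,
        raw_score = 10 + 2 * z)
    }
  }
  dplyr::bind_rows(rows)
}
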