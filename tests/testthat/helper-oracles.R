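# Independent oracles and fixture builders used across the suite.

# Build a meg_network directly from a symmetric weight matrix (weights may be
# signed; zero means no edge).
make_network <- function(W, band = "test", K = 100, alpha = 0.01,
                         roles = NULL) {
  n <- nrow(W)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = idx[, 1], to = idx[, 2],
    weight = abs(W[idx]), sign = ifelse(W[idx] >= 0, 1L, -1L),
    r = W[idx], tp = NA_real_
  )
  structure(
    list(
      n_nodes = n, node_labels = sprintf("node%02d", seq_len(n)),
      node_roles = roles %||% rep("other", n),
      edges = edges, alpha = alpha, K = K, band = band, k_edges = nrow(edges)
    ),
    class = "meg_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Floyd-Warshall all-pairs shortest paths with 1/w edge lengths, then the
# L = 0 convention for unreachable pairs and the diagonal.
fw_path_oracle <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W != 0] <- 1 / W[W != 0]
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D[!is.finite(D)] <- 0
  D
}

# Triple-loop geometric-mean clustering with max-weight normalization.
brute_clustering_oracle <- function(W) {
  n <- nrow(W)
  if (all(W == 0)) {
    return(rep(0, n))
  }
  Wn <- W / max(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(Wn[i, ] > 0)
    d <- length(nb)
    if (d < 2) next
    acc <- 0
    for (j in nb) {
      for (k in nb) {
        if (j != k && Wn[j, k] > 0) {
          acc <- acc + (Wn[i, j] * Wn[j, k] * Wn[k, i])^(1 / 3)
        }
      }
    }
    ci[i] <- acc / (d * (d - 1))
  }
  ci
}

# Random undirected weighted graph as a symmetric weight matrix.
random_weight_matrix <- function(n, p_edge = 0.4, w_min = 0.1, w_max = 1) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[runif(length(up)) < p_edge]
  W[on] <- runif(length(on), w_min, w_max)
  W + t(W)
}

# Hand pooled-variance two-sample t statistic.
pooled_t_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Tiny single-band coupled-pair simulation config.
pair_config <- function(rho, band = "alpha", fs = 100, duration = 61,
                        jitter = 0) {
  sim_config(
    n_nodes = 2, fs = fs, duration = duration, bands = meg_bands(band),
    planted_edges = tibble::tibble(
      node_i = 1L, node_j = 2L, band = band, rho = rho
    ),
    rho_jitter_sd = jitter
  )
}

# Reduced-scale beta-band study configuration used by the end-to-end
# recovery checks: an eight-node frontal clique (rho 0.6, scaled by 0.4 in
# the impaired group) plus an unaffected four-node anchor clique and one
# uncoupled pcc node; K = 60 s x fs samples. The frontal-rich design mirrors
# the spatial extent of the frontal connectivity effect being emulated.
beta_study_config <- function(fs = 1000, duration = 61) {
  frontal_pairs <- t(utils::combn(1:8, 2))
  anchor_pairs <- t(utils::combn(9:12, 2))
  sim_config(
    n_nodes = 13,
    node_roles = c(rep("frontal", 8), rep("other", 4), "pcc"),
    fs = fs, duration = duration, bands = meg_bands("beta"),
    planted_edges = dplyr::bind_rows(
      tibble::tibble(
        node_i = frontal_pairs[, 1], node_j = frontal_pairs[, 2],
        band = "beta", rho = 0.6
      ),
      tibble::tibble(
        node_i = anchor_pairs[, 1], node_j = anchor_pairs[, 2],
        band = "beta", rho = 0.6
      )
    ),
    group_effects = tibble::tibble(
      group = "fsiq_lt80", role_a = "frontal", role_b = "frontal",
      band = "beta", multiplier = 0.4
    )
  )
}

# Run one synthetic cohort through segment -> band -> network -> metrics.
cohort_metrics <- function(cohort, band, alpha = 0.01, segment_s = 60) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(k) {
    seg <- select_clean_segment(cohort$recording[[k]], NULL, length_s = segment_s)
    net <- threshold_network(
      pairwise_correlation(segment_bandpass(seg, band)),
      alpha = alpha
    )
    dplyr::mutate(
      graph_metrics(net, subject_id = cohort$subject_id[k]),
      group = cohort$group[k]
    )
  })
}
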