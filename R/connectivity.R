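#' Pairwise source correlation matrix
#'
#' Pearson correlation of every pair of virtual-sensor signals over the
#' analysis segment: R = cov(Xa, Xb) / (S_Xa S_Xb), with the sample
#' covariance in the numerator and the sample standard deviations below.
#' The number of data points K in the segment is recorded for the t-type
#' threshold statistic.
#'
#' @param seg A `meg_segment` (typically band-limited via
#'   [segment_bandpass()]).
#' @param effective_k If `TRUE`, additionally estimate per-pair effective
#'   sample counts that discount the autocorrelation of band-limited signals
#'   (Bartlett's formula); stored as matrix `Keff`. Off by default: the
#'   published analysis uses the raw sample count.
#' @param max_lag_s Truncation lag in seconds for the autocorrelation sums
#'   (default 1 s).
#' @return An object of class `meg_connectivity`: fields `R` (symmetric,
#'   unit diagonal), `K`, `band`, `node_labels`, `node_roles`, `fs` and
#'   optionally `Keff`.
#' @export
pairwise_correlation <- function(seg, effective_k = FALSE, max_lag_s = 1) {
  stopifnot(inherits(seg, "meg_segment"))
  if (seg$K < 3) abort("At least K = 3 samples are required")
  sds <- apply(seg$data, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "Zero-variance channel(s): ",
      paste(seg$node_labels[sds == 0], collapse = ", ")
    ))
  }
  R <- cor(seg$data)
  diag(R) <- 1
  dimnames(R) <- list(seg$node_labels, seg$node_labels)
  cm <- structure(
    list(
      R = R, K = seg$K, band = seg$band,
      node_labels = seg$node_labels, node_roles = seg$node_roles, fs = seg$fs
    ),
    class = "meg_connectivity"
  )
  if (effective_k) cm$Keff <- effective_samples(seg, max_lag_s = max_lag_s)
  cm
}

#' Effective sample counts under autocorrelation
#'
#' Band-limited signals are serially correlated, so the nominal K samples of
#' a segment carry fewer independent observations. Bartlett's approximation
#' gives `var(R_ab) ~ (1/K) * sum_tau r_a(tau) r_b(tau)` under independence,
#' so the effective count is `K / sum_tau (1 - |tau|/K) r_a(tau) r_b(tau)`
#' with the autocorrelations truncated at `max_lag_s`.
#'
#' @param seg A `meg_segment`.
#' @param max_lag_s Truncation lag in seconds.
#' @return A symmetric N x N matrix of effective sample counts (diagonal K).
#' @export
effective_samples <- function(seg, max_lag_s = 1) {
  K <- seg$K
  M <- min(K - 1L, round(max_lag_s * seg$fs))
  ac <- apply(seg$data, 2, function(x) {
    as.numeric(acf(x, lag.max = M, plot = FALSE, demean = TRUE)$acf)
  }) # (M+1) x N, lag 0 first
  taper <- 1 - (0:M) / K
  n_nodes <- ncol(seg$data)
  keff <- matrix(K, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      s <- sum(taper * ac[, i] * ac[, j]) * 2 - 1 # two-sided sum, lag 0 once
      keff[i, j] <- keff[j, i] <- K / max(s, 1)
    }
  }
  dimnames(keff) <- list(seg$node_labels, seg$node_labels)
  keff
}

#' t-type threshold statistic for a correlation
#'
#' `TP = R * sqrt(K - 2) / sqrt(1 - R^2)`: under the null of no coupling TP
#' follows a Student t distribution with K - 2 degrees of freedom, so
#' comparing |TP| against [tp_critical()] thresholds edges at a chosen
#' significance level. Vectorized over `R`.
#'
#' @param R Correlation(s) in `[-1, 1]`; `|R| = 1` maps to signed infinity.
#' @param K Number of data points (>= 3).
#' @return TP value(s), same sign as `R`.
#' @examples
#' tp_statistic(0.6, 4) # ~ 1.0607
#' @export
tp_statistic <- function(R, K) {
  if (any(K < 3)) abort("K must be at least 3")
  if (any(abs(R) > 1)) abort("|R| must not exceed 1")
  out <- ifelse(abs(R) == 1, sign(R) * Inf, R * sqrt(K - 2) / sqrt(1 - R^2))
  out
}

#' Critical TP value at a significance level
#'
#' Two-sided Student t critical value with K - 2 degrees of freedom; an edge
#' is retained when |TP| exceeds it (default alpha = 0.01, the published
#' threshold).
#'
#' @param alpha Two-sided significance level (default 0.01).
#' @param K Number of data points (>= 3).
#' @return The critical value (0 when `alpha = 1`).
#' @export
tp_critical <- function(alpha = 0.01, K) {
  if (any(K < 3)) abort("K must be at least 3")
  qt(1 - alpha / 2, df = K - 2)
}

#' Threshold a correlation matrix into a signed weighted network
#'
#' Retains edge (i, j) iff `|TP(R_ij, K)| > tp_critical(alpha, K)`. Retained
#' edges carry weight `|R_ij|` and the sign of `R_ij` (positive and negative
#' connections are distinguished downstream).
#'
#' @param cm A `meg_connectivity`.
#' @param alpha Two-sided significance level (default 0.01).
#' @param use_effective_k Use the Bartlett effective sample counts (requires
#'   `pairwise_correlation(effective_k = TRUE)`); default `FALSE`, matching
#'   the published raw-K rule.
#' @return An object of class `meg_network`: fields `n_nodes`,
#'   `node_labels`, `node_roles`, `edges` (tibble `from`, `to`, `weight`,
#'   `sign`, `r`, `tp`; `from < to`), `alpha`, `K`, `band`, `k_edges`.
#' @export
threshold_network <- function(cm, alpha = 0.01, use_effective_k = FALSE) {
  stopifnot(inherits(cm, "meg_connectivity"))
  n <- nrow(cm$R)
  if (use_effective_k && is.null(cm$Keff)) {
    abort("No effective sample counts present; rerun pairwise_correlation(effective_k = TRUE)")
  }
  idx <- which(upper.tri(cm$R), arr.ind = TRUE)
  r <- cm$R[idx]
  kmat <- if (use_effective_k) cm$Keff[idx] else rep(cm$K, nrow(idx))
  tp <- tp_statistic(r, pmax(kmat, 3))
  crit <- tp_critical(alpha, pmax(kmat, 3))
  keep <- abs(tp) > crit
  edges <- tibble::tibble(
    from = unname(idx[keep, 1]), to = unname(idx[keep, 2]),
    weight = abs(r[keep]), sign = ifelse(r[keep] >= 0, 1L, -1L),
    r = r[keep], tp = tp[keep]
  )
  structure(
    list(
      n_nodes = n, node_labels = cm$node_labels, node_roles = cm$node_roles,
      edges = edges, alpha = alpha, K = cm$K, band = cm$band,
      k_edges = nrow(edges)
    ),
    class = "meg_network"
  )
}

#' @export
print.meg_network <- function(x, ...) {
  cat(sprintf(
    "<meg_network> %d nodes, %d edges (%d+, %d-), band %s, alpha %g, K %d\n",
    x$n_nodes, x$k_edges, sum(x$edges$sign > 0), sum(x$edges$sign < 0),
    x$band, x$alpha, x$K
  ))
  invisible(x)
}

#' Write / read a thresholded network as a weighted edge list
#'
#' Tab-delimited columns `node_i`, `node_j`, `weight`, `sign`, `tp`, after a
#' header comment line `# N=<n> K=<K> band=<band> alpha=<alpha>`.
#'
#' @param net A `meg_network`.
#' @param path File path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `meg_network` (node roles restored from an optional
#'   `# roles=` comment).
#' @export
write_network <- function(net, path) {
  header <- sprintf(
    "# N=%d K=%d band=%s alpha=%g\n# roles=%s",
    net$n_nodes, net$K, net$band, net$alpha, paste(net$node_roles, collapse = ",")
  )
  writeLines(c(
    header, "node_i\tnode_j\tweight\tsign\ttp",
    sprintf(
      "%d\t%d\t%.12g\t%d\t%.12g",
      net$edges$from, net$edges$to, net$edges$weight, net$edges$sign, net$edges$tp
    )
  ), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[1]
  get_field <- function(name, line) sub(paste0(".*", name, "=([^ ]+).*"), "\\1", line)
  n <- as.integer(get_field("N", hdr))
  K <- as.integer(get_field("K", hdr))
  band <- get_field("band", hdr)
  alpha <- as.numeric(get_field("alpha", hdr))
  roles <- strsplit(get_field("roles", lines[2]), ",")[[1]]
  body <- lines[-(1:2)]
  edges <- readr::read_tsv(I(paste(body, collapse = "\n")),
    col_types = "iidid", progress = FALSE
  )
  edges <- tibble::tibble(
    from = edges$node_i, to = edges$node_j, weight = edges$weight,
    sign = as.integer(edges$sign), r = edges$weight * edges$sign, tp = edges$tp
  )
  structure(
    list(
      n_nodes = n, node_labels = sprintf("node%02d", seq_len(n)),
      node_roles = roles, edges = edges, alpha = alpha, K = K, band = band,
      k_edges = nrow(edges)
    ),
    class = "meg_network"
  )
}
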