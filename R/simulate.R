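#' Simulation configuration for synthetic virtual-sensor cohorts
#'
#' Defines the study conditions emulated by the generator: a 120 s recording
#' at 6000 Hz, seven analysis bands, planted pairwise coupling with a known
#' expected band-filtered correlation, and group-level coupling reductions in
#' the impaired group. Each node's signal is a sum over bands of band-limited
#' Gaussian components; a planted edge (i, j, band, rho) draws the two nodes'
#' components for that band from a joint Gaussian with correlation rho, so
#' the expected band-filtered Pearson correlation equals rho exactly (the
#' band filter is linear and common to both channels).
#'
#' @param n_nodes Number of virtual sensors.
#' @param node_roles Character vector of roles (`"frontal"`, `"pcc"`,
#'   `"other"`), one per node.
#' @param fs Sampling rate in Hz (default 6000).
#' @param duration Recording length in seconds (default 120).
#' @param bands Band table as from [meg_bands()].
#' @param planted_edges Tibble `(node_i, node_j, band, rho)` with
#'   `rho` in `[0, 1)`; pairs may appear in several bands.
#' @param group_effects Tibble `(group, role_a, role_b, band, multiplier)`;
#'   a planted edge whose endpoint roles match `role_a`/`role_b` (either
#'   order) in that band has its rho multiplied for subjects of that group.
#' @param noise_sd Total background standard deviation in nominal pT
#'   (default 0.5; split evenly in power across bands).
#' @param rho_jitter_sd Between-subject SD of planted rho (default 0.05,
#'   truncated to keep rho in `[0, 0.95]`).
#' @param seed Base seed for deterministic generation.
#' @return A list of class `meg_sim_config`.
#' @seealso [default_sim_config()] for the packaged study conditions.
#' @export
sim_config <- function(n_nodes,
                       node_roles = rep("other", n_nodes),
                       fs = 6000,
                       duration = 120,
                       bands = meg_bands(),
                       planted_edges = NULL,
                       group_effects = NULL,
                       noise_sd = 0.5,
                       rho_jitter_sd = 0.05,
                       seed = 1L) {
  stopifnot(n_nodes >= 2, length(node_roles) == n_nodes)
  if (fs <= 2 * max(bands$hi)) {
    abort(sprintf(
      "fs = %g Hz cannot represent the %g Hz band edge (need fs > %g)",
      fs, max(bands$hi), 2 * max(bands$hi)
    ))
  }
  if (is.null(planted_edges)) {
    planted_edges <- tibble::tibble(
      node_i = integer(), node_j = integer(), band = character(), rho = numeric()
    )
  }
  if (nrow(planted_edges)) {
    if (any(planted_edges$rho < 0 | planted_edges$rho >= 1)) {
      abort("Planted rho must be in [0, 1)")
    }
    if (!all(planted_edges$band %in% as.character(bands$band))) {
      abort("Planted edge refers to a band absent from the configuration")
    }
    if (any(planted_edges$node_i == planted_edges$node_j)) {
      abort("Planted edges must join distinct nodes")
    }
  }
  if (is.null(group_effects)) {
    group_effects <- tibble::tibble(
      group = character(), role_a = character(), role_b = character(),
      band = character(), multiplier = numeric()
    )
  }
  structure(
    list(
      n_nodes = n_nodes, node_roles = node_roles, fs = fs, duration = duration,
      bands = bands, planted_edges = planted_edges, group_effects = group_effects,
      noise_sd = noise_sd, rho_jitter_sd = rho_jitter_sd, seed = as.integer(seed)
    ),
    class = "meg_sim_config"
  )
}

#' Packaged study conditions for the synthetic cohort
#'
#' Twelve nodes: four frontal (a beta-band clique at rho = 0.6), two
#' posterior-cingulate (coupled at rho = 0.6 in the ripple and fast-ripple
#' bands), and six unaffected nodes carrying anchor structure in the same
#' bands (a beta triangle and ripple / fast-ripple triangles at rho = 0.6)
#' plus sparse background coupling (rho = 0.4) in the remaining bands. The
#' impaired group's coupling is multiplied by 0.4 on frontal-frontal beta
#' edges and pcc-pcc ripple / fast-ripple edges; the non-impaired and
#' control groups are unchanged.
#'
#' @param fs,duration,bands,seed,... Overrides passed to [sim_config()].
#' @return A `meg_sim_config`.
#' @export
default_sim_config <- function(fs = 6000, duration = 120, bands = meg_bands(),
                               seed = 1L, ...) {
  roles <- c(rep("frontal", 4), rep("pcc", 2), rep("other", 6))
  pairs <- function(idx) t(utils::combn(idx, 2))
  frontal <- pairs(1:4)
  edges <- dplyr::bind_rows(
    tibble::tibble(
      node_i = frontal[, 1], node_j = frontal[, 2], band = "beta", rho = 0.6
    ),
    tibble::tibble(node_i = 5L, node_j = 6L, band = c("ripple", "fast_ripple"), rho = 0.6),
    tibble::tibble(
      node_i = c(7L, 8L, 7L), node_j = c(8L, 9L, 9L), band = "beta", rho = 0.6
    ),
    tibble::tibble(
      node_i = c(10L, 11L, 10L), node_j = c(11L, 12L, 12L), band = "ripple", rho = 0.6
    ),
    tibble::tibble(
      node_i = c(10L, 11L, 10L), node_j = c(11L, 12L, 12L), band = "fast_ripple", rho = 0.6
    ),
    tibble::tibble(
      node_i = c(7L, 8L, 9L, 7L), node_j = c(10L, 11L, 12L, 11L),
      band = c("delta", "theta", "alpha", "gamma"), rho = 0.4
    )
  )
  edges <- edges[edges$band %in% as.character(bands$band), ]
  effects <- tibble::tibble(
    group = "fsiq_lt80",
    role_a = c("frontal", "pcc", "pcc"),
    role_b = c("frontal", "pcc", "pcc"),
    band = c("beta", "ripple", "fast_ripple"),
    multiplier = 0.4
  )
  effects <- effects[effects$band %in% as.character(bands$band), ]
  sim_config(
    n_nodes = 12, node_roles = roles, fs = fs, duration = duration,
    bands = bands, planted_edges = edges, group_effects = effects,
    seed = seed, ...
  )
}

# Evaluate RNG-dependent code under a derived seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-band node correlation matrix implied by the planted edges.
band_correlation_matrix <- function(config, band_name) {
  sigma <- diag(config$n_nodes)
  e <- config$planted_edges[config$planted_edges$band == band_name, ]
  if (nrow(e)) {
    sigma[cbind(e$node_i, e$node_j)] <- e$rho
    sigma[cbind(e$node_j, e$node_i)] <- e$rho
  }
  sigma
}

#' Generate one synthetic virtual-sensor recording
#'
#' @param config A `meg_sim_config`.
#' @param seed Seed overriding `config$seed`.
#' @return A [meg_recording()]; identical config and seed give bit-identical
#'   output.
#' @examples
#' cfg <- sim_config(
#'   n_nodes = 3, fs = 200, duration = 10, bands = meg_bands("alpha"),
#'   planted_edges = tibble::tibble(node_i = 1, node_j = 2, band = "alpha", rho = 0.6)
#' )
#' rec <- generate_recording(cfg)
#' @export
generate_recording <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "meg_sim_config"))
  n <- round(config$fs * config$duration)
  n_bands <- nrow(config$bands)
  band_sd <- config$noise_sd / sqrt(n_bands)
  with_seed(seed, {
    data <- matrix(0, n, config$n_nodes)
    for (b in seq_len(n_bands)) {
      band <- config$bands[b, ]
      sigma <- band_correlation_matrix(config, as.character(band$band))
      chol_u <- tryCatch(chol(sigma), error = function(e) {
        abort(paste0(
          "Planted correlations for band ", band$band,
          " are not jointly realizable (matrix not positive definite)"
        ))
      })
      z <- matrix(rnorm(n * config$n_nodes), n, config$n_nodes) %*% chol_u
      gain <- bandpass_gain(n, config$fs, band$lo, band$hi)
      scale <- band_sd / sqrt(gain_power_fraction(gain))
      data <- data + apply_fft_gain(z, gain) * scale
    }
    meg_recording(data, config$fs, node_roles = config$node_roles)
  })
}

# Apply group effects and truncated-Gaussian between-subject jitter to the
# planted rho values; returns a modified config.
subject_config <- function(config, group, subject_seed) {
  edges <- config$planted_edges
  if (nrow(edges)) {
    eff <- config$group_effects[config$group_effects$group == group, ]
    if (nrow(eff)) {
      role_i <- config$node_roles[edges$node_i]
      role_j <- config$node_roles[edges$node_j]
      for (k in seq_len(nrow(eff))) {
        hit <- edges$band == eff$band[k] &
          ((role_i == eff$role_a[k] & role_j == eff$role_b[k]) |
            (role_i == eff$role_b[k] & role_j == eff$role_a[k]))
        edges$rho[hit] <- edges$rho[hit] * eff$multiplier[k]
      }
    }
    if (config$rho_jitter_sd > 0) {
      jitter <- with_seed(subject_seed, rnorm(nrow(edges), 0, config$rho_jitter_sd))
      edges$rho <- pmin(pmax(edges$rho + jitter, 0), 0.95)
    }
  }
  config$planted_edges <- edges
  config
}

#' Generate a synthetic cohort of recordings
#'
#' Draws `n_per_group` recordings per group, applying each group's coupling
#' multipliers and a per-subject truncated-Gaussian jitter of the planted
#' correlations. Subject seeds are derived deterministically from the base
#' seed, group index and subject index.
#'
#' @param config A `meg_sim_config` with `group_effects` covering `groups`.
#' @param n_per_group Subjects per group (scalar or one per group).
#' @param groups Group labels (default the impaired, non-impaired and
#'   healthy-control groups).
#' @param seed Base seed overriding `config$seed`.
#' @return A tibble with columns `subject_id`, `group`, `seed` and a
#'   list-column `recording`.
#' @export
generate_cohort <- function(config, n_per_group,
                            groups = c("fsiq_lt80", "fsiq_gt80", "hc"),
                            seed = config$seed) {
  n_per_group <- rep(as.integer(n_per_group), length.out = length(groups))
  rows <- purrr::map2(seq_along(groups), n_per_group, function(g, n_g) {
    if (n_g == 0) {
      return(NULL)
    }
    purrr::map(seq_len(n_g), function(s) {
      subj_seed <- (seed + 7919L * g + s) %% .Machine$integer.max
      cfg <- subject_config(config, groups[g], subj_seed + 1L)
      tibble::tibble(
        group = groups[g],
        seed = subj_seed,
        recording = list(generate_recording(cfg, seed = subj_seed))
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    return(tibble::tibble(
      subject_id = integer(), group = character(), seed = integer(),
      recording = list()
    ))
  }
  out$subject_id <- seq_len(nrow(out))
  out[, c("subject_id", "group", "seed", "recording")]
}

#' Inject epileptiform spike transients into a recording
#'
#' Adds brief (default 60 ms) high-amplitude biphasic transients at Poisson
#' event times on every channel and annotates them. Events of amplitude
#' above the artifact threshold (6 pT) double as injectable artifacts.
#'
#' @param rec A `meg_recording`.
#' @param rate Events per minute (0 leaves the recording unchanged).
#' @param amplitude Peak amplitude in pT; should exceed the background SD.
#' @param seed Seed for event times.
#' @param width_s Transient duration in seconds (default 0.06, i.e. < 100 ms).
#' @param kind Annotation kind, `"spike"` or `"artifact"`.
#' @return The recording with transients added and annotations extended.
#' @export
inject_spikes <- function(rec, rate, amplitude, seed = 1L,
                          width_s = 0.06, kind = "spike") {
  stopifnot(inherits(rec, "meg_recording"))
  if (rate == 0) {
    return(rec)
  }
  dur <- recording_duration(rec)
  with_seed(seed, {
    n_events <- rpois(1, rate * dur / 60)
    if (n_events == 0) {
      return(rec)
    }
    onsets <- sort(runif(n_events, 0, dur - width_s))
    n_w <- max(4L, round(width_s * rec$fs))
    t_w <- seq_len(n_w) / n_w
    # biphasic: one full sine cycle under a Hann window
    shape <- sin(2 * pi * t_w) * 0.5 * (1 - cos(2 * pi * t_w))
    shape <- shape / max(abs(shape)) * amplitude
    for (onset in onsets) {
      i0 <- floor(onset * rec$fs) + 1L
      idx <- i0:(i0 + n_w - 1L)
      rec$data[idx, ] <- rec$data[idx, ] + shape
    }
    rec$annotations <- dplyr::bind_rows(
      rec$annotations,
      tibble::tibble(onset_s = onsets, duration_s = width_s, kind = kind)
    )
    rec
  })
}
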