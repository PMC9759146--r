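#' Construct a virtual-sensor recording
#'
#' A recording bundles a samples-by-nodes matrix of source-level ("virtual
#' sensor") time series with its sampling rate, node labels and roles, and a
#' table of annotated events (spikes, artifacts). Amplitudes are in nominal
#' picotesla so the 6 pT artifact-exclusion rule is meaningful.
#'
#' @param data Numeric matrix, samples in rows, nodes in columns.
#' @param fs Sampling rate in Hz.
#' @param node_labels Character vector of node names (defaults `node01`...).
#' @param node_roles Character vector of node roles (e.g. `"frontal"`,
#'   `"pcc"`, `"other"`); used by regional connectivity summaries.
#' @param annotations Tibble with columns `onset_s`, `duration_s`, `kind`.
#' @return An object of class `meg_recording`.
#' @export
meg_recording <- function(data, fs,
                          node_labels = NULL,
                          node_roles = NULL,
                          annotations = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) abort("Recording data must be finite")
  if (fs <= 0) abort("Sampling rate must be positive")
  n_nodes <- ncol(data)
  if (is.null(node_labels)) node_labels <- sprintf("node%02d", seq_len(n_nodes))
  if (is.null(node_roles)) node_roles <- rep("other", n_nodes)
  stopifnot(length(node_labels) == n_nodes, length(node_roles) == n_nodes)
  if (is.null(annotations)) {
    annotations <- tibble::tibble(
      onset_s = numeric(), duration_s = numeric(), kind = character()
    )
  }
  dur <- nrow(data) / fs
  if (nrow(annotations) > 0 &&
    any(annotations$onset_s < 0 | annotations$onset_s + annotations$duration_s > dur)) {
    abort("Annotations must lie within [0, duration]")
  }
  structure(
    list(
      data = data, fs = fs, node_labels = node_labels,
      node_roles = node_roles, annotations = annotations
    ),
    class = "meg_recording"
  )
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf(
    "<meg_recording> %d nodes x %.6g s @ %g Hz (%d samples), %d annotation(s)\n",
    ncol(x$data), nrow(x$data) / x$fs, x$fs, nrow(x$data), nrow(x$annotations)
  ))
  roles <- table(x$node_roles)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

recording_duration <- function(rec) nrow(rec$data) / rec$fs

#' Write / read a recording on disk
#'
#' Two container formats are supported. `"text"` writes the data matrix as a
#' tab-delimited file (one row per sample, one column per node) next to a
#' YAML sidecar `<path>.meta.yaml` holding the sampling rate, labels, roles
#' and annotations. `"binary"` writes a little-endian double array preceded by
#' a 3-line ASCII header (`shape: <samples> <nodes>`, `dtype: float64`,
#' `fs: <Hz>`) with the same YAML sidecar.
#'
#' @param rec A `meg_recording`.
#' @param path Output path (data file; the sidecar adds `.meta.yaml`).
#' @param format `"text"` or `"binary"`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `meg_recording`.
#' @export
write_recording <- function(rec, path, format = c("binary", "text")) {
  format <- match.arg(format)
  meta <- list(
    fs = rec$fs,
    node_labels = rec$node_labels,
    node_roles = rec$node_roles,
    annotations = as.list(as.data.frame(rec$annotations))
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  if (format == "text") {
    readr::write_tsv(
      tibble::as_tibble(rec$data, .name_repair = ~ rec$node_labels),
      path,
      progress = FALSE
    )
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(
      sprintf("shape: %d %d", nrow(rec$data), ncol(rec$data)),
      "dtype: float64",
      sprintf("fs: %.10g", rec$fs)
    ), con)
    writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("binary", "text")) {
  format <- match.arg(format)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  ann <- meta$annotations
  annotations <- if (length(ann$onset_s)) {
    tibble::tibble(
      onset_s = as.numeric(ann$onset_s),
      duration_s = as.numeric(ann$duration_s),
      kind = as.character(ann$kind)
    )
  } else {
    NULL
  }
  if (format == "text") {
    data <- as.matrix(readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_double()), progress = FALSE
    ))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- c(readLines(con, n = 3))
    shape <- as.integer(strsplit(sub("shape: ", "", header[1]), " ")[[1]])
    data <- matrix(
      readBin(con, "double", n = prod(shape), size = 8, endian = "little"),
      nrow = shape[1], ncol = shape[2]
    )
  }
  meg_recording(
    data, as.numeric(meta$fs),
    node_labels = as.character(meta$node_labels),
    node_roles = as.character(meta$node_roles),
    annotations = annotations
  )
}
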