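# File formats.  Matrices travel as dense CSV (no row names, V1..Vn header)
# or Matrix Market; spike trains as two-column CSV (neuron, time_ms) with
# 1-based neuron ids (row i of a matrix = source neuron i throughout).

#' Write / read a connectivity or adjacency matrix
#'
#' Lossless round-trip of a square signed matrix at full precision.  CSV files
#' are dense with a header row; Matrix Market files use the coordinate format
#' (explicit zeros, if present, are dropped from the support on read, with a
#' message).  Matrix Market support requires the Matrix package.
#'
#' @param matrix square numeric matrix.
#' @param path file path.
#' @param format `"csv"` or `"matrix-market"`.
#' @return `read_matrix` returns the matrix; `write_matrix` returns `path`
#'   invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("csv", "matrix-market")) {
  format <- match.arg(format)
  stopifnot(is.matrix(matrix))
  if (format == "csv") {
    chr <- matrix(sprintf("%.17g", matrix), nrow(matrix))  # bitwise round-trip
    utils::write.table(chr, path, sep = ",", row.names = FALSE, quote = FALSE,
                       col.names = paste0("V", seq_len(ncol(matrix))))
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("Matrix Market output needs the Matrix package")
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                                            "generalMatrix"), "TsparseMatrix"), path)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, format = c("csv", "matrix-market")) {
  format <- match.arg(format)
  if (format == "csv") {
    raw <- utils::read.csv(path, header = TRUE, colClasses = "character")
    m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)),
                                 nrow = nrow(raw)))
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell at data row %d, column %d of %s",
                   bad[1], bad[2], path))
    }
    if (nrow(m) != ncol(m))
      stop(sprintf("matrix in %s is not square (%d x %d)",
                   path, nrow(m), ncol(m)))
    m
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("Matrix Market input needs the Matrix package")
    sm <- Matrix::readMM(path)
    if (nrow(sm) != ncol(sm))
      stop(sprintf("matrix in %s is not square (%d x %d)",
                   path, nrow(sm), ncol(sm)))
    n_explicit <- length(sm@x)
    m <- as.matrix(sm)
    if (sum(m != 0) < n_explicit)
      message("explicit zeros in ", path, " dropped from the support")
    m
  }
}

#' Write / read spike trains
#'
#' Two-column CSV `(neuron, time_ms)` with 1-based neuron ids; the number of
#' neurons and the duration are stored in `#`-comment header lines so a
#' recording round-trips exactly.
#'
#' @param spikes a [spike_train_set()].
#' @param path file path.
#' @return `read_spikes` returns a [spike_train_set()]; `write_spikes`
#'   returns `path` invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_neurons=%d", spikes$n_neurons),
               sprintf("# duration_s=%.10g", spikes$duration),
               "neuron,time_ms"), con)
  if (nrow(spikes$spikes) > 0)
    utils::write.table(spikes$spikes, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @param n_neurons,duration overrides when the file has no header comments.
#' @export
read_spikes <- function(path, n_neurons = NULL, duration = NULL) {
  hdr <- readLines(path, n = 5)
  for (h in hdr[startsWith(hdr, "#")]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    if (kv[1] == "n_neurons" && is.null(n_neurons)) n_neurons <- as.integer(kv[2])
    if (kv[1] == "duration_s" && is.null(duration)) duration <- as.numeric(kv[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  names(df) <- c("neuron", "time_ms")
  if (nrow(df) > 0 && any(df$time_ms < 0)) stop("negative spike times in ", path)
  if (is.null(n_neurons)) n_neurons <- if (nrow(df)) max(df$neuron) else 0L
  if (is.null(duration)) duration <- if (nrow(df)) max(df$time_ms) / 1000 else 0
  if (nrow(df) > 0 && (any(df$neuron < 1) || any(df$neuron > n_neurons)))
    stop(sprintf("neuron id outside [1, %d] in %s", n_neurons, path))
  if (nrow(df) > 0 && is.unsorted(df$time_ms))
    warning("spike times in ", path, " were unsorted; sorted on read")
  spike_train_set(df, n_neurons, duration)
}

#' Serialize a structural network
#'
#' Weights as a matrix file, delays as a CSV sidecar (source, target,
#' delay_ms), and a JSON metadata file (topology tag, seed, sizes).
#'
#' @param net a [structural_network()].
#' @param basename path prefix; files `<basename>_weights.csv` (or `.mtx`),
#'   `<basename>_delays.csv`, `<basename>_meta.json` are created.
#' @param format matrix format for the weights.
#' @return `read_structural_network` returns the [structural_network()];
#'   `write_structural_network` returns `basename` invisibly.
#' @export
write_structural_network <- function(net, basename,
                                     format = c("csv", "matrix-market")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "structural_network"))
  ext <- if (format == "csv") "csv" else "mtx"
  write_matrix(net$adjacency, paste0(basename, "_weights.", ext), format)
  idx <- which(net$adjacency != 0, arr.ind = TRUE)
  utils::write.csv(data.frame(source = idx[, 1], target = idx[, 2],
                              delay_ms = net$delays[idx]),
                   paste0(basename, "_delays.csv"), row.names = FALSE)
  jsonlite::write_json(list(topology = net$topology, seed = net$seed,
                            n_neurons = net$n_neurons,
                            n_excitatory = net$n_excitatory),
                       paste0(basename, "_meta.json"), auto_unbox = TRUE)
  invisible(basename)
}

#' @rdname write_structural_network
#' @export
read_structural_network <- function(basename,
                                    format = c("csv", "matrix-market")) {
  format <- match.arg(format)
  ext <- if (format == "csv") "csv" else "mtx"
  w <- read_matrix(paste0(basename, "_weights.", ext), format)
  meta <- jsonlite::read_json(paste0(basename, "_meta.json"))
  dl_df <- utils::read.csv(paste0(basename, "_delays.csv"))
  dl <- matrix(0L, nrow(w), ncol(w))
  dl[cbind(dl_df$source, dl_df$target)] <- as.integer(dl_df$delay_ms)
  structural_network(w, dl, meta$n_excitatory, meta$topology,
                     as.integer(meta$seed))
}

#' Run manifest
#'
#' Provenance record for a pipeline run: configuration snapshot, seeds and
#' stage parameters, serializable to JSON so any output can be reproduced.
#'
#' @param config named list of stage configurations.
#' @param seeds named list/vector of seeds.
#' @param files named list of input/output paths.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seeds = list(), files = list()) {
  structure(list(package_version = as.character(utils::packageVersion("ddtnet")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = config, seeds = seeds, files = files),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
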