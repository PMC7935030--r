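#' Write / read a recording
#'
#' Text format: one header line `fs=<Hz> n_nodes=<n> labels=<a,b,...>`
#' followed by a nodes x samples tab-delimited numeric matrix. `format =
#' "binary"` uses an RDS container instead (exact round trip, faster).
#'
#' @param rec a [recording()].
#' @param path output path.
#' @param format `"text"` or `"binary"`.
#' @export
write_recording <- function(rec, path, format = c("text", "binary")) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  if (format == "binary") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  header <- sprintf("fs=%.10g n_nodes=%d labels=%s", rec$fs,
                    nrow(rec$data), paste(rec$labels, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(format(rec$data, digits = 15, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE,
              sep = "\t")
  invisible(path)
}

#' @rdname write_recording
#' @return `read_recording` returns a `recording`.
#' @export
read_recording <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    rec <- readRDS(path)
    if (!inherits(rec, "recording"))
      stop_param("'%s' does not contain a recording", path)
    return(rec)
  }
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec(
    "^fs=([0-9.eE+-]+) n_nodes=([0-9]+) labels=(.*)$", header))[[1]]
  if (length(m) != 4)
    stop_param("malformed recording header at %s line 1: '%s'", path,
               header)
  fs <- as.numeric(m[2])
  n <- as.integer(m[3])
  labels <- strsplit(m[4], ",", fixed = TRUE)[[1]]
  dat <- as.matrix(read.table(path, skip = 1, sep = "\t"))
  dimnames(dat) <- NULL
  if (nrow(dat) != n)
    stop_param("recording '%s': header says %d nodes, found %d rows",
               path, n, nrow(dat))
  recording(dat, fs, labels)
}

#' Write / read a network weight matrix
#'
#' Square tab-delimited matrix with a node-label header row.
#'
#' @param net square weight matrix.
#' @param path file path.
#' @export
write_network <- function(net, path) {
  check_square_matrix(net)
  labels <- rownames(net) %||% paste0("node", seq_len(nrow(net)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  write.table(format(net, digits = 15, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE,
              sep = "\t")
  invisible(path)
}

#' @rdname write_network
#' @return `read_network` returns the weight matrix with labels as dimnames.
#' @export
read_network <- function(path) {
  labels <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  m <- as.matrix(read.table(path, skip = 1, sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop_param("network file '%s' is not square (%d x %d)", path,
               nrow(m), ncol(m))
  if (length(labels) != nrow(m))
    stop_param("network file '%s': %d labels for %d nodes", path,
               length(labels), nrow(m))
  dimnames(m) <- list(labels, labels)
  m
}

#' Edge-list view of a network
#'
#' @param net square weight matrix.
#' @return data frame (`source`, `target`, `weight`) of nonzero edges.
#' @export
network_to_edgelist <- function(net) {
  check_square_matrix(net)
  labels <- rownames(net) %||% paste0("node", seq_len(nrow(net)))
  idx <- which(net != 0 & row(net) != col(net))
  n <- nrow(net)
  data.frame(source = labels[((idx - 1L) %% n) + 1L],
             target = labels[((idx - 1L) %/% n) + 1L],
             weight = net[idx])
}

#' Cohort manifest (subject, session, file path)
#'
#' @param manifest data frame with columns `subject`, `session`, `path`.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("subject", "session", "path") %in% names(manifest)))
  write.table(manifest, path, row.names = FALSE, sep = ",", quote = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @return `read_manifest` returns the manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("subject", "session", "path") %in% names(m)))
    stop_param("manifest '%s' must have subject, session, path columns",
               path)
  m
}
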