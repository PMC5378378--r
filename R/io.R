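#' Write a binary state series as TSV
#'
#' One row per time bin, N columns of -1/+1, preceded by a header line
#' `# N=<n> bin=<dt>`.
#'
#' @param series a `state_series`.
#' @param path output file.
#' @export
write_state_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d bin=%g", ncol(series),
                     attr(series, "bin_duration")), con)
  utils::write.table(unclass(series), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a binary state series from TSV
#' @param path input file written by [write_state_series()] (header
#'   optional).
#' @return a `state_series`.
#' @export
read_state_series <- function(path) {
  first <- readLines(path, n = 1)
  bin <- 1
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("bin=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) bin <- as.numeric(m[2])
  }
  m <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  state_series(m, bin_duration = bin, origin = path)
}

#' Write a numeric matrix as TSV with a JSON header comment
#' @param m matrix.
#' @param path output file.
#' @param meta named list serialized into the `#` header line.
#' @export
write_matrix_tsv <- function(m, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta$nrow <- nrow(m); meta$ncol <- ncol(m)
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path input file.
#' @return matrix with attribute `meta`.
#' @export
read_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1)
  meta <- NULL
  if (startsWith(first, "# "))
    meta <- jsonlite::fromJSON(sub("^# ", "", first))
  m <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  attr(m, "meta") <- meta
  m
}

#' Serialize a clustering result to JSON
#' @param clusters a `cluster_result`.
#' @param path output file.
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_result"))
  obj <- list(centroids = unname(apply(clusters$centroids, 1, as.integer,
                                       simplify = FALSE)),
              masses = clusters$masses,
              assignments = clusters$assignments,
              params = clusters$params[c("n0", "convergence_fraction",
                                         "refine_radius", "mass_cutoff",
                                         "seed")],
              converged = clusters$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a clustering result from JSON
#' @param path file written by [write_clusters()].
#' @return a `cluster_result`.
#' @export
read_clusters <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cen <- obj$centroids
  if (is.list(cen)) cen <- do.call(rbind, lapply(cen, as.integer))
  storage.mode(cen) <- "integer"
  .cluster_result(cen, as.numeric(obj$masses),
                  as.integer(obj$assignments),
                  obj$params, isTRUE(obj$converged))
}

#' Write a spike raster as two-column text
#' @param raster data.frame with `time` (ms) and `id` columns.
#' @param path output file.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster[, c("time", "id")], path, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column spike raster
#' @param path input file (time_ms neuron_id per line).
#' @return data.frame with `time` and `id`.
#' @export
read_raster <- function(path) {
  m <- utils::read.table(path, col.names = c("time", "id"))
  m
}

#' Write a label sequence as single-column text
#' @param seq a `label_sequence`.
#' @param path output file.
#' @export
write_labels <- function(seq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alphabet=%d", attr(seq, "alphabet_size")), con)
  writeLines(as.character(as.integer(seq)), con)
  invisible(path)
}

#' Read a label sequence written by [write_labels()]
#' @param path input file.
#' @return a `label_sequence`.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  K <- NULL
  if (startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("alphabet=([0-9]+)", lines[1]))[[1]]
    if (length(m) == 2) K <- as.integer(m[2])
    lines <- lines[-1]
  }
  v <- as.integer(lines)
  label_sequence(v, alphabet_size = if (is.null(K)) max(v) else K)
}
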