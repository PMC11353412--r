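# Delimited-text I/O for matrices, clouds, diagrams and policies.
# Matrices are written at full double precision (17 significant digits) so
# a write/read round trip is exact.

#' Read / write a matrix as delimited text
#'
#' One row per line, fields separated by `delim`, written with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param path file path.
#' @param x numeric matrix.
#' @param delim field delimiter.
#' @return `read_matrix_txt` returns a numeric matrix;
#'   `write_matrix_txt` returns `path` invisibly.
#' @export
write_matrix_txt <- function(x, path, delim = "\t") {
  .check_matrix(x)
  lines <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path, delim = "\t") {
  rows <- strsplit(readLines(path), delim, fixed = TRUE)
  nc <- unique(lengths(rows))
  if (length(nc) != 1)
    stop("ragged rows in ", path, call. = FALSE)
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (any(!is.finite(m))) stop("non-finite entries in ", path, call. = FALSE)
  m
}

#' Persist / load a matrix cloud as a directory of text files
#'
#' Members are written as `member_000001.txt`, ... next to a
#' `provenance.json` sidecar holding the generation parameters, so a
#' persisted cloud can be audited or regenerated.
#'
#' @param cloud a [matrix_cloud()].
#' @param dir directory path (created if missing).
#' @param delim field delimiter.
#' @return `read_cloud_dir` returns a `matrix_cloud`; `write_cloud_dir`
#'   returns `dir` invisibly.
#' @export
write_cloud_dir <- function(cloud, dir, delim = "\t") {
  cloud <- as_matrix_cloud(cloud)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cloud))
    write_matrix_txt(cloud[[i]], file.path(dir, sprintf("member_%06d.txt", i)),
                     delim)
  prov <- attr(cloud, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cloud_dir
#' @export
read_cloud_dir <- function(dir, delim = "\t") {
  files <- sort(list.files(dir, pattern = "^member_\\d+\\.txt$",
                           full.names = TRUE))
  if (!length(files)) stop("no member files in ", dir, call. = FALSE)
  members <- lapply(files, read_matrix_txt, delim = delim)
  provfile <- file.path(dir, "provenance.json")
  prov <- if (file.exists(provfile)) jsonlite::read_json(provfile,
                                                         simplifyVector = TRUE)
  matrix_cloud(members, provenance = prov)
}

#' Read / write a persistence diagram as CSV
#'
#' Columns `dimension, birth, death`; essential classes use the token
#' `"inf"` in the death column.
#'
#' @param diagram a persistence diagram.
#' @param path file path.
#' @return `read_diagram_csv` returns a `"persistence_diagram"`;
#'   `write_diagram_csv` returns `path` invisibly.
#' @export
write_diagram_csv <- function(diagram, path) {
  diagram <- as_persistence_diagram(diagram)
  out <- data.frame(dimension = diagram$dimension,
                    birth = sprintf("%.17g", diagram$birth),
                    death = ifelse(is.infinite(diagram$death), "inf",
                                   sprintf("%.17g", diagram$death)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_diagram_csv
#' @export
read_diagram_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  death <- ifelse(tolower(raw$death) == "inf", Inf, as.numeric(raw$death))
  structure(data.frame(dimension = as.integer(raw$dimension),
                       birth = as.numeric(raw$birth),
                       death = death),
            class = c("persistence_diagram", "data.frame"))
}

#' Serialise / restore a surgery policy
#'
#' Flat key/value JSON (variant plus its parameters), the format the
#' command-line front end accepts.
#'
#' @param policy a [surgery_policy()].
#' @param path file path.
#' @return `read_policy` returns a `surgery_policy`; `write_policy`
#'   returns `path` invisibly.
#' @export
write_policy <- function(policy, path) {
  if (!inherits(policy, "surgery_policy"))
    stop("'policy' must be a surgery_policy", call. = FALSE)
  jsonlite::write_json(unclass(policy), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(surgery_policy, p)
}
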