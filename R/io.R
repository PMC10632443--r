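#' Read and write dense community matrices as CSV
#'
#' Matrices are stored as plain comma-separated values with no header:
#' row `i` holds the effects on species `i` (`M[i,j]` at row `i`, column
#' `j`), written at full double precision so a write/read round trip is
#' exact. `write_matrix_csv()` can attach a JSON sidecar
#' (`<path>.json`) carrying the generating spec and diagonal scheme.
#'
#' @param path File path.
#' @param M Matrix or `community_matrix` to write.
#' @param sidecar Write the JSON metadata sidecar when `M` is a
#'   `community_matrix` (default `TRUE`).
#' @param square Require the file to be square (default `TRUE`).
#' @return `read_matrix_csv()` returns a numeric matrix;
#'   `write_matrix_csv()` the path, invisibly.
#' @export
read_matrix_csv <- function(path, square = TRUE) {
  if (!file.exists(path)) {
    stop_ecoreact("file not found: ", path, class = "ecoreact_io")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    stop_ecoreact("ragged CSV: row ", bad, " has ", ncols[bad],
                  " fields, expected ", ncols[1], class = "ecoreact_io")
  }
  M <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE))
  if (any(is.na(M))) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop_ecoreact("non-numeric cell at row ", bad[1], ", column ", bad[2],
                  class = "ecoreact_io")
  }
  if (square && nrow(M) != ncol(M)) {
    stop_ecoreact("matrix is ", nrow(M), " x ", ncol(M),
                  ", expected square", class = "ecoreact_io")
  }
  M
}

#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(path, M, sidecar = TRUE) {
  V <- as_matrix_values(M)
  writeLines(apply(V, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  }), path)
  if (sidecar && inherits(M, "community_matrix") && !is.null(M$spec)) {
    meta <- list(schema_version = 1L,
                 spec = spec_to_list(M$spec),
                 diagonal_scheme = if (is.null(M$diagonal_scheme)) NULL else
                   unclass(M$diagonal_scheme))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

spec_to_list <- function(spec) {
  list(S = spec$S, C = spec$C, sigma = spec$sigma, d = spec$d,
       interaction_type = spec$interaction_type,
       mix = if (is.null(spec$mix)) NULL else as.list(spec$mix),
       z_dist = spec$z_dist$name, seed = spec$seed)
}

#' Serialise a niche web description to JSON
#'
#' Writes `eta`, `radius`, `centre`, `beta_param` and the adjacency matrix
#' (row-major 0/1 list) of a niche-model web.
#'
#' @param path Output path.
#' @param web A `niche_web_spec` (the `niche` element of a
#'   [generate_niche()] result).
#' @return The path, invisibly.
#' @export
write_niche_web <- function(path, web) {
  stopifnot(inherits(web, "niche_web_spec"))
  jsonlite::write_json(list(schema_version = 1L,
                            eta = web$eta, radius = web$radius,
                            centre = web$centre,
                            beta_param = web$beta_param,
                            adjacency = as.integer(t(web$adjacency))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
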