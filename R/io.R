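# Delimited-text interfaces: response matrices, ilr-transformed matrices,
# possible-means exports and grid specifications from YAML/JSON config.

#' Transform a matrix of Likert responses to the ilr scale
#'
#' Column-wise pipeline for raw questionnaire data: integer responses
#' `1..K` are embedded into the trait scale (`r*`) and carried to the real
#' line by the two-part ilr transform.
#'
#' @param responses Integer matrix or data frame (rows = respondents,
#'   columns = items) with entries in `1..K`.
#' @param scale A [likert_scale()].
#' @return Numeric matrix of the same shape with attributes `K` and `p`.
#' @export
responses_to_ilr <- function(responses, scale) {
  stopifnot(inherits(scale, "likert_scale"))
  m <- as.matrix(responses)
  out <- matrix(scale$r_ilr[response_to_star_index(m, scale)],
                nrow(m), ncol(m), dimnames = dimnames(m))
  attr(out, "K") <- scale$K
  attr(out, "p") <- scale$p
  out
}

response_to_star_index <- function(m, scale) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m != round(m)) ||
      any(m < 1 | m > scale$K))
    stop(sprintf("responses must be integers in 1..%d", scale$K),
         call. = FALSE)
  as.integer(m)
}

#' Read / write delimited response or ilr matrices
#'
#' `write_ilr_matrix()` writes an ilr-transformed matrix as CSV preceded by
#' a one-line comment header recording the scale parameters
#' (`# K=<K> p=<p>`); `read_responses()` reads a delimited integer response
#' matrix (rows = respondents, columns = items), skipping comment lines.
#'
#' @param x Numeric matrix from [responses_to_ilr()].
#' @param file Path of the file to write or read.
#' @param scale A [likert_scale()] (for the header).
#' @param sep Field separator; default comma.
#' @return `read_responses()` returns an integer matrix;
#'   `write_ilr_matrix()` returns `file` invisibly.
#' @export
write_ilr_matrix <- function(x, file, scale, sep = ",") {
  stopifnot(inherits(scale, "likert_scale"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# K=%d p=%g", scale$K, scale$p), con)
  utils::write.table(x, con, sep = sep, row.names = FALSE,
                     col.names = !is.null(colnames(x)))
  invisible(file)
}

#' @rdname write_ilr_matrix
#' @param header Logical: does the data file carry a column-name row?
#' @export
read_responses <- function(file, sep = ",", header = FALSE) {
  m <- as.matrix(utils::read.table(file, sep = sep, header = header,
                                   comment.char = "#"))
  storage.mode(m) <- "integer"
  m
}

#' Export a possible-means lattice as CSV
#'
#' Writes the lattice values as a single-column CSV whose header names the
#' scale representation (e.g. `ilr`).
#'
#' @param means A [possible_means()] object.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_possible_means <- function(means, file) {
  stopifnot(inherits(means, "possible_means"))
  df <- stats::setNames(data.frame(means$values), means$scale_label)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a grid specification from a YAML or JSON config file
#'
#' The file may set any subset of the [grid_spec()] arguments (`variances`,
#' `correlations`, `Ks`, `Is`, `ps`, `dgps`, `n_pairs`, `n_runs`, `alpha`,
#' `master_seed`); unset fields keep the full-study defaults. Requires the
#' `yaml` or `jsonlite` package, respectively.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [grid_spec()].
#' @export
grid_spec_from_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(file)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package",
           call. = FALSE)
    jsonlite::fromJSON(file)
  } else {
    stop("unsupported config format: ", ext, call. = FALSE)
  }
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  allowed <- names(formals(grid_spec))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown grid fields in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(grid_spec, cfg)
}
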