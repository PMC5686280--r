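#' Read and write covariance matrices and parameter-vector tables
#'
#' Plain-CSV covariance matrices carry the parameter names as header and
#' a square numeric body.  The NONMEM `.cov` dialect (a `TABLE` header
#' line, a `NAME` column, whitespace-separated values) is also read.
#' Parameter-vector tables (one row per vector, columns named by
#' parameter, optional `ofv` column — the rawres layout) round-trip
#' through CSV so any method's output can be consumed interchangeably.
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @return `read_cov_csv()`: named square matrix.
#' @export
read_cov_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m))
    stop("covariance CSV must be square (got ", nrow(m), " x ", ncol(m), ")")
  rownames(m) <- colnames(m)
  m
}

#' @rdname io
#' @param cov covariance matrix with column names.
#' @export
write_cov_csv <- function(cov, path) {
  utils::write.csv(as.data.frame(cov), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @return `read_nonmem_cov()`: named square matrix (the `NAME` column
#'   supplies row names; rows/columns ordered as in the file).
#' @export
read_nonmem_cov <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^TABLE", lines)]
  lines <- lines[nzchar(trimws(lines))]
  con <- textConnection(lines)
  on.exit(close(con))
  d <- utils::read.table(con, header = TRUE, check.names = FALSE)
  if (!"NAME" %in% names(d)) stop("no NAME column: not a NONMEM .cov table")
  nm <- d$NAME
  m <- as.matrix(d[setdiff(names(d), "NAME")])
  if (nrow(m) != ncol(m)) stop(".cov table body must be square")
  dimnames(m) <- list(nm, colnames(m))
  m
}

#' @rdname io
#' @return `read_vectors_csv()`: matrix of parameter vectors; an `ofv`
#'   column, if present, is returned as attribute `"ofv"`.
#' @export
read_vectors_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  ofv <- NULL
  if ("ofv" %in% names(d)) {
    ofv <- d$ofv
    d$ofv <- NULL
  }
  m <- as.matrix(d)
  attr(m, "ofv") <- ofv
  m
}

#' @rdname io
#' @param vectors matrix of parameter vectors (rows).
#' @param ofv optional per-vector OFV column.
#' @export
write_vectors_csv <- function(vectors, path, ofv = NULL) {
  d <- as.data.frame(vectors)
  if (!is.null(ofv)) d$ofv <- ofv
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param ws a [weight_sample()] result.
#' @return `write_sample_csv()`: writes the per-iteration samples table
#'   (parameters, ofv, dofv, relpdf, ir).
#' @export
write_sample_csv <- function(ws, path) {
  d <- as.data.frame(ws$vectors)
  d$ofv <- ws$ofv
  d$dofv <- ws$dofv
  d$relpdf <- ws$relpdf
  d$ir <- ws$ir
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param rs a [resample()] result.
#' @export
write_resamples_csv <- function(rs, path) {
  d <- as.data.frame(rs$vectors)
  d$draw_order <- seq_len(nrow(d))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
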