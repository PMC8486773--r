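#' Read and write accession-indexed matrices as TSV
#'
#' Matrices are stored with a first column `accession` followed by one
#' column per channel/timepoint; values round-trip through the pair of
#' functions.
#'
#' @param m Numeric matrix with accession rownames.
#' @param path File path.
#' @return `read_profile_matrix` returns the matrix; `write_profile_matrix`
#'   returns `path` invisibly.
#' @export
write_profile_matrix <- function(m, path) {
  df <- data.frame(accession = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "accession") stop("first column must be 'accession'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$accession
  m
}

#' Read and write PSM tables as TSV
#'
#' The PSM schema uses the exact column names of
#' [generate_psm_table()]; missing reporter intensities are written as
#' empty strings.
#'
#' @param table PSM data frame.
#' @param path File path.
#' @return `read_psm_table` returns the data frame.
#' @export
write_psm_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  df$quan_info <- as.character(df$quan_info)
  df$is_contaminant <- as.logical(df$is_contaminant)
  df
}

#' Read and write flat key-value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' returned as character and coerced by the consumer.
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  setNames(vapply(kv, `[`, character(1), 2),
           vapply(kv, `[`, character(1), 1))
}

#' @rdname read_config_file
#' @param config Named vector or list of scalar values.
#' @export
write_config_file <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}
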