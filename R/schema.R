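#' Default subcellular compartment schema
#'
#' The eleven subcellular niches used for organelle classification of
#' fractionation profiles: mitochondria, endoplasmic reticulum, Golgi
#' apparatus, lysosome, peroxisome, plasma membrane, nucleus, nucleolus,
#' chromatin, ribosome and cytosol.
#'
#' @return Character vector of compartment labels, in canonical order.
#' @export
#' @examples
#' lopit_compartments()
lopit_compartments <- function() {
  c("mitochondria", "ER", "Golgi apparatus", "lysosome", "peroxisome",
    "PM", "nucleus", "nucleolus", "chromatin", "ribosome", "cytosol")
}

#' Construct a marker map
#'
#' A marker map associates curated marker proteins with their (single, known)
#' subcellular compartment. Markers act as the labelled training set for the
#' semi-supervised classifier; only proteins of unambiguous, single-location
#' residence should be used.
#'
#' @param accession Character vector of protein accessions.
#' @param compartment Character vector of compartment labels, one per
#'   accession.
#' @param schema Ordered character vector of allowed compartment labels.
#'   Defaults to [lopit_compartments()]; labels present in `compartment` but
#'   absent from the schema are an error.
#' @return A `marker_map` data frame with columns `accession` and
#'   `compartment` and a `"schema"` attribute.
#' @export
marker_map <- function(accession, compartment, schema = NULL) {
  accession <- as.character(accession)
  compartment <- as.character(compartment)
  if (length(accession) != length(compartment))
    stop("`accession` and `compartment` must have equal length")
  if (anyDuplicated(accession))
    stop("marker accessions must be unique (one label per marker)")
  if (is.null(schema)) schema <- unique(compartment)
  bad <- setdiff(compartment, schema)
  if (length(bad))
    stop("marker labels not in schema: ", paste(bad, collapse = ", "))
  mm <- data.frame(accession = accession, compartment = compartment,
                   stringsAsFactors = FALSE)
  attr(mm, "schema") <- schema
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' @export
print.marker_map <- function(x, ...) {
  cat("Marker map:", nrow(x), "markers,",
      length(attr(x, "schema")), "compartments\n")
  print(table(x$compartment)[attr(x, "schema")])
  invisible(x)
}

#' Read / write a marker list
#'
#' Marker lists are stored as tab-separated files with columns `accession`
#' and `compartment` (one marker per row).
#'
#' @param path Path to a TSV file.
#' @param schema Compartment schema passed to [marker_map()]; `NULL` derives
#'   it from the file in order of first appearance.
#' @return For `read_markers`, a [marker_map()]; `write_markers` is called
#'   for its side effect and returns `path` invisibly.
#' @export
read_markers <- function(path, schema = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("accession", "compartment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("marker file is missing column(s): ", paste(miss, collapse = ", "))
  marker_map(df$accession, df$compartment, schema = schema)
}

#' @rdname read_markers
#' @param markers A [marker_map()].
#' @export
write_markers <- function(markers, path) {
  write.table(markers[, c("accession", "compartment")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
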