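#' Marker panel: the ordered inventory of SSR markers and their allele labels
#'
#' A `marker_panel` describes the column layout of an [allele_matrix()]: an
#' ordered set of SSR markers, each carrying an ordered set of allele labels
#' (conventionally fragment sizes in base pairs), plus optional repeat motif
#' and fragment size range metadata.
#'
#' @param markers character vector of marker names (unique, non-empty).
#' @param alleles list of character vectors, one per marker, giving the
#'   ordered allele labels (unique within a marker, at least one per marker).
#' @param motif optional character vector of repeat motifs, e.g. `"(TTC)10"`.
#' @param size_range optional list of length-2 integer vectors
#'   `c(low, high)` with `low <= high`, or `NULL` entries when unknown.
#'
#' @return An object of class `marker_panel`: a list with elements
#'   `markers` (character), `alleles` (named list), `motif` (named
#'   character), `size_range` (named list).
#' @examples
#' marker_panel(c("IBS11", "IBS14"),
#'              alleles = list(c("224", "227", "230"), c("188", "212")))
#' @export
marker_panel <- function(markers, alleles, motif = NULL, size_range = NULL) {
  markers <- as.character(markers)
  if (length(markers) == 0L) stop("a marker panel needs at least one marker")
  if (anyDuplicated(markers)) {
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  if (!is.list(alleles) || length(alleles) != length(markers)) {
    stop("`alleles` must be a list with one entry per marker")
  }
  alleles <- lapply(alleles, as.character)
  names(alleles) <- markers
  for (m in markers) {
    a <- alleles[[m]]
    if (length(a) < 1L) stop("marker ", m, " has no allele labels")
    if (anyDuplicated(a)) stop("duplicate allele labels within marker ", m)
  }
  if (is.null(motif)) motif <- rep(NA_character_, length(markers))
  motif <- as.character(motif)
  if (length(motif) != length(markers)) {
    stop("`motif` must have one entry per marker")
  }
  names(motif) <- markers
  if (is.null(size_range)) {
    size_range <- rep(list(NULL), length(markers))
  }
  if (length(size_range) != length(markers)) {
    stop("`size_range` must have one entry per marker")
  }
  names(size_range) <- markers
  for (m in markers) {
    sr <- size_range[[m]]
    if (!is.null(sr)) {
      sr <- as.integer(sr)
      if (length(sr) != 2L || anyNA(sr) || sr[1] > sr[2]) {
        stop("size_range for marker ", m, " must be c(low, high), low <= high")
      }
      size_range[[m]] <- sr
    }
  }
  structure(list(markers = markers, alleles = alleles,
                 motif = motif, size_range = size_range),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$markers), " markers, ",
      sum(lengths(x$alleles)), " allele columns\n", sep = "")
  for (m in utils::head(x$markers, 10L)) {
    cat("  ", m, ": ", length(x$alleles[[m]]), " alleles",
        if (!is.na(x$motif[[m]])) paste0(" [", x$motif[[m]], "]") else "",
        "\n", sep = "")
  }
  if (length(x$markers) > 10L) cat("  ...\n")
  invisible(x)
}

#' Column keys of a marker panel
#'
#' Keys follow the `<marker>_<allele>` convention used in the delimited
#' matrix format, markers in panel order and alleles in label order.
#'
#' @param panel a [marker_panel()].
#' @return character vector of column keys.
#' @export
panel_columns <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  unlist(lapply(panel$markers,
                function(m) paste(m, panel$alleles[[m]], sep = "_")),
         use.names = FALSE)
}

#' Marker of each panel column
#' @param panel a [marker_panel()].
#' @return character vector, parallel to [panel_columns()].
#' @export
panel_column_markers <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  rep(panel$markers, lengths(panel$alleles[panel$markers]))
}

# Infer a panel from "<marker>_<allele>" column keys: the allele label is the
# part after the LAST underscore, so marker names may themselves contain
# underscores.  Column order defines marker and allele order.
panel_from_columns <- function(keys) {
  keys <- as.character(keys)
  if (length(keys) == 0L) stop("no genotype columns to infer a panel from")
  bad <- !grepl("_", keys, fixed = TRUE)
  if (any(bad)) {
    stop("column name(s) not in <marker>_<allele> form: ",
         paste(utils::head(keys[bad], 5L), collapse = ", "))
  }
  marker <- sub("_[^_]*$", "", keys)
  allele <- sub("^.*_", "", keys)
  um <- unique(marker)
  # markers must form contiguous blocks for the panel order to be well defined
  runs <- rle(marker)$values
  if (anyDuplicated(runs)) {
    stop("columns of marker(s) ",
         paste(unique(runs[duplicated(runs)]), collapse = ", "),
         " are not contiguous in the header")
  }
  alle <- split(allele, factor(marker, levels = um))
  sr <- lapply(um, function(m) {
    v <- suppressWarnings(as.integer(alle[[m]]))
    if (anyNA(v)) NULL else c(min(v), max(v))
  })
  marker_panel(um, alle[um], size_range = sr)
}

# TRUE when two panels have identical marker sets, allele sets and order.
panels_identical <- function(a, b) {
  identical(a$markers, b$markers) && identical(a$alleles, b$alleles)
}
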