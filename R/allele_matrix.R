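#' Allele matrix: dominant-scored SSR fingerprints
#'
#' The central container of the package: samples (rows) by
#' marker-allele columns (in panel order), each cell scored present (1),
#' absent (0) or missing (`NA`, serialized as 9).  Dominant scoring is the
#' standard convention for polyploids such as hexaploid sweetpotato, where
#' allele dosage cannot be read off a gel.
#'
#' Missing data are block-structured: a locus either failed to amplify for a
#' sample (whole marker block missing) or was scored in full.  Cells are
#' stored per allele, but [validate_matrix()] reports blocks that mix
#' missing and scored cells, and analysis code treats such blocks as missing
#' (see [block_normalize()]).
#'
#' Row names are sample ids.  A sample id is either a bare accession id
#' (`"CIP400001"`) or an accession id qualified by sample source
#' (`"CIP400001|mother"`, `"CIP400001|invitro"`), which is how paired
#' mother-plant / in-vitro fingerprints of one accession coexist.
#'
#' @param scores integer/numeric matrix with values in \{0, 1, NA\};
#'   row names are sample ids (unique), column count must equal the number
#'   of panel columns.
#' @param panel a [marker_panel()]; if `NULL`, inferred from `colnames(scores)`.
#'
#' @return An object of class `allele_matrix`: list with elements `scores`
#'   (integer matrix, dimnames set), `panel`.
#' @seealso [read_matrix()], [write_matrix()], [validate_matrix()],
#'   [subset_matrix()], [merge_matrices()]
#' @export
allele_matrix <- function(scores, panel = NULL) {
  scores <- as.matrix(scores)
  if (is.null(panel)) {
    if (is.null(colnames(scores))) {
      stop("either a panel or column names are required")
    }
    panel <- panel_from_columns(colnames(scores))
  }
  stopifnot(inherits(panel, "marker_panel"))
  keys <- panel_columns(panel)
  if (ncol(scores) != length(keys)) {
    stop("scores has ", ncol(scores), " columns but the panel defines ",
         length(keys))
  }
  if (!is.null(colnames(scores)) && !identical(colnames(scores), keys)) {
    if (!setequal(colnames(scores), keys)) {
      stop("score columns do not match the panel's marker_allele keys")
    }
    scores <- scores[, keys, drop = FALSE]
  }
  storage.mode(scores) <- "integer"
  ok <- scores %in% c(0L, 1L) | is.na(scores)
  if (!all(ok)) {
    stop("scores must be 0, 1 or NA; offending value at position ",
         which(!ok)[1])
  }
  ids <- rownames(scores)
  if (nrow(scores) > 0L) {
    if (is.null(ids)) stop("row names (sample ids) are required")
    if (anyDuplicated(ids)) {
      stop("duplicate sample ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  colnames(scores) <- keys
  structure(list(scores = scores, panel = panel), class = "allele_matrix")
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat("<allele_matrix> ", nrow(x$scores), " samples x ", ncol(x$scores),
      " allele columns (", length(x$panel$markers), " markers); ",
      sum(is.na(x$scores)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.allele_matrix <- function(x) dim(x$scores)

#' Sample ids of an allele matrix
#' @param m an [allele_matrix()].
#' @return character vector of sample ids (row order).
#' @export
sample_ids <- function(m) {
  stopifnot(inherits(m, "allele_matrix"))
  rownames(m$scores) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a sample id into accession id and sample source
#'
#' @param ids character vector of sample ids, `"id"` or `"id|source"`.
#' @return data.frame with columns `sample_id`, `accession_id`,
#'   `sample_source` (`"unspecified"` when unqualified).
#' @export
parse_sample_ids <- function(ids) {
  ids <- as.character(ids)
  has <- grepl("|", ids, fixed = TRUE)
  acc <- ifelse(has, sub("\\|.*$", "", ids), ids)
  src <- ifelse(has, sub("^.*\\|", "", ids), "unspecified")
  data.frame(sample_id = ids, accession_id = acc, sample_source = src,
             stringsAsFactors = FALSE)
}

# Column index blocks per marker, as a named list of integer vectors.
marker_blocks <- function(panel) {
  cm <- panel_column_markers(panel)
  split(seq_along(cm), factor(cm, levels = panel$markers))
}

#' Force block-level missingness
#'
#' Any (sample, marker) block containing at least one missing cell is set
#' entirely missing.  Downstream statistics assume loci were either scored
#' in full or failed to amplify; this makes partially scored blocks conform
#' to that convention (conservatively, by discarding the partial scores).
#'
#' @param m an [allele_matrix()].
#' @return an [allele_matrix()] with homogeneous blocks.
#' @export
block_normalize <- function(m) {
  stopifnot(inherits(m, "allele_matrix"))
  sc <- m$scores
  for (idx in marker_blocks(m$panel)) {
    blk <- sc[, idx, drop = FALSE]
    bad <- rowSums(is.na(blk)) > 0L
    if (any(bad)) sc[bad, idx] <- NA_integer_
  }
  allele_matrix(sc, m$panel)
}

# Logical sample x marker matrix: TRUE where the block is fully scored.
scored_blocks <- function(m) {
  blocks <- marker_blocks(m$panel)
  out <- vapply(blocks, function(idx) {
    rowSums(is.na(m$scores[, idx, drop = FALSE])) == 0L
  }, logical(nrow(m$scores)))
  if (nrow(m$scores) == 1L) out <- matrix(out, nrow = 1L,
                                          dimnames = list(sample_ids(m),
                                                          names(blocks)))
  out
}

#' Read a 0/1/9 fingerprint table
#'
#' Reads the canonical delimited format: a comma-separated table whose first
#' column (`accession_id`) holds sample ids and whose remaining columns are
#' `<marker>_<allele>` keys with cells in \{0, 1, 9\} (9 = missing).
#'
#' @param path file path.
#' @param panel optional [marker_panel()]; inferred from the header when
#'   omitted.  When supplied, its columns must match the file header.
#' @param sep field separator (default comma).
#' @return a validated [allele_matrix()].
#' @export
read_matrix <- function(path, panel = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 1L) stop("file has no columns: ", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate accession/sample id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- matrix(!(cells %in% c("0", "1", "9")), nrow(cells), ncol(cells))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("cell outside {0,1,9} at row '", ids[w[1L]], "', column '",
         colnames(cells)[w[2L]], "': ", cells[w[1L], w[2L]])
  }
  sc <- matrix(as.integer(cells), nrow = nrow(cells),
               dimnames = list(ids, colnames(cells)))
  sc[sc == 9L] <- NA_integer_
  allele_matrix(sc, panel)
}

#' Write a fingerprint table in canonical 0/1/9 form
#'
#' Inverse of [read_matrix()]: header `accession_id,<marker>_<allele>,...`,
#' one row per sample, missing cells written as 9.  Column order is panel
#' order, so write-after-read is byte identical on canonical files.
#'
#' @param m an [allele_matrix()].
#' @param path file path.
#' @param sep field separator (default comma).
#' @return invisibly, `path`.
#' @export
write_matrix <- function(m, path, sep = ",") {
  stopifnot(inherits(m, "allele_matrix"))
  sc <- m$scores
  sc[is.na(sc)] <- 9L
  df <- data.frame(accession_id = sample_ids(m), sc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate an allele matrix
#'
#' Pure reporting, never mutates or throws: lists (sample, marker) blocks
#' mixing missing and scored cells, markers monomorphic over scored samples
#' (all-present or all-absent in every scored block; retained because they
#' still enter Jaccard denominators), and samples missing at every marker.
#'
#' @param m an [allele_matrix()].
#' @return list of class `matrix_validation` with data.frame `mixed_blocks`
#'   (`sample_id`, `marker`), character vectors `monomorphic_markers` and
#'   `all_missing_samples`, and logical `clean`.
#' @export
validate_matrix <- function(m) {
  stopifnot(inherits(m, "allele_matrix"))
  blocks <- marker_blocks(m$panel)
  ids <- sample_ids(m)
  mixed <- list()
  mono <- character(0)
  for (mk in names(blocks)) {
    blk <- m$scores[, blocks[[mk]], drop = FALSE]
    nmiss <- rowSums(is.na(blk))
    bad <- nmiss > 0L & nmiss < ncol(blk)
    if (any(bad)) {
      mixed[[mk]] <- data.frame(sample_id = ids[bad], marker = mk,
                                stringsAsFactors = FALSE)
    }
    scored <- blk[nmiss == 0L, , drop = FALSE]
    if (nrow(scored) > 0L) {
      vals <- unique(as.vector(scored))
      # monomorphic: every scored sample shows the identical banding pattern
      if (nrow(unique(scored)) == 1L || length(vals) == 1L) {
        mono <- c(mono, mk)
      }
    }
  }
  mixed <- if (length(mixed)) do.call(rbind, unname(mixed)) else
    data.frame(sample_id = character(0), marker = character(0),
               stringsAsFactors = FALSE)
  allmiss <- ids[rowSums(!is.na(m$scores)) == 0L & ncol(m$scores) > 0L]
  out <- list(mixed_blocks = mixed, monomorphic_markers = mono,
              all_missing_samples = allmiss,
              clean = nrow(mixed) == 0L && length(mono) == 0L &&
                length(allmiss) == 0L)
  class(out) <- "matrix_validation"
  out
}

#' @export
print.matrix_validation <- function(x, ...) {
  cat("<matrix_validation> ", if (x$clean) "clean" else "issues found", "\n",
      sep = "")
  if (nrow(x$mixed_blocks)) {
    cat("  mixed missing/scored blocks: ", nrow(x$mixed_blocks), "\n")
  }
  if (length(x$monomorphic_markers)) {
    cat("  monomorphic markers: ",
        paste(x$monomorphic_markers, collapse = ", "), "\n")
  }
  if (length(x$all_missing_samples)) {
    cat("  all-missing samples: ", length(x$all_missing_samples), "\n")
  }
  invisible(x)
}

#' Subset an allele matrix by sample id
#'
#' @param m an [allele_matrix()].
#' @param ids character vector of sample ids; output rows follow `ids`.
#' @return an [allele_matrix()] restricted to `ids`, same panel.
#' @export
subset_matrix <- function(m, ids) {
  stopifnot(inherits(m, "allele_matrix"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, sample_ids(m))
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(utils::head(unknown, 5L),
                                         collapse = ", "))
  }
  allele_matrix(m$scores[ids, , drop = FALSE], m$panel)
}

#' Merge two allele matrices over a shared marker set
#'
#' Used for joint analyses across collections genotyped with the same
#' marker panel but possibly different observed allele inventories.  The
#' merged panel takes, per marker, the union of allele labels (labels of
#' `a` first, then novel labels of `b`).  For an allele unknown to one
#' source, that source's samples are scored absent at it when they scored
#' the marker at all (the fragment was observably not there), and missing
#' when the whole block is missing.
#'
#' @param a,b [allele_matrix()] objects with identical marker name sets.
#' @param labels length-2 character vector used to qualify sample ids that
#'   collide across the two inputs (`"<label>:<id>"`).
#' @return merged [allele_matrix()]; rows of `a` then rows of `b`.
#' @export
merge_matrices <- function(a, b, labels = c("a", "b")) {
  stopifnot(inherits(a, "allele_matrix"), inherits(b, "allele_matrix"))
  if (!setequal(a$panel$markers, b$panel$markers)) {
    stop("incompatible panels: marker name sets differ (",
         paste(setdiff(a$panel$markers, b$panel$markers), collapse = ", "),
         " | ",
         paste(setdiff(b$panel$markers, a$panel$markers), collapse = ", "),
         ")")
  }
  markers <- a$panel$markers
  alle <- lapply(markers, function(mk) {
    c(a$panel$alleles[[mk]],
      setdiff(b$panel$alleles[[mk]], a$panel$alleles[[mk]]))
  })
  panel <- marker_panel(markers, alle)

  ids_a <- sample_ids(a)
  ids_b <- sample_ids(b)
  clash <- intersect(ids_a, ids_b)
  if (length(clash)) {
    ids_a[ids_a %in% clash] <- paste0(labels[1L], ":",
                                      ids_a[ids_a %in% clash])
    ids_b[ids_b %in% clash] <- paste0(labels[2L], ":",
                                      ids_b[ids_b %in% clash])
  }

  expand <- function(m, ids) {
    keys <- panel_columns(panel)
    out <- matrix(NA_integer_, nrow = length(ids), ncol = length(keys),
                  dimnames = list(ids, keys))
    out[, colnames(m$scores)] <- m$scores
    # novel alleles: absent (0) wherever the source scored the marker block
    sb <- scored_blocks(m)
    for (mk in markers) {
      novel <- setdiff(panel$alleles[[mk]], m$panel$alleles[[mk]])
      if (length(novel)) {
        cols <- paste(mk, novel, sep = "_")
        out[sb[, mk], cols] <- 0L
      }
    }
    out
  }
  merged <- rbind(expand(a, ids_a), expand(b, ids_b))
  allele_matrix(merged, panel)
}
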