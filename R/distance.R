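#' Pairwise Jaccard dissimilarity of dominant fingerprints
#'
#' For each sample pair, over the allele columns where both samples have a
#' scored marker block: `a` = both present, `b`/`c` = present in one only.
#' The Jaccard dissimilarity is `1 - a / (a + b + c)`; columns where both
#' samples lack the fragment do not enter (shared absence of a band is not
#' evidence of relatedness).  Missing blocks are handled pairwise-complete:
#' a column is used for a pair exactly when both members scored its marker.
#'
#' @param m an [allele_matrix()] with at least two samples.
#' @return object of class `dist_matrix`: list with `ids`, `d` (symmetric
#'   numeric matrix, 0 diagonal, `NA` where a pair shares no informative
#'   column, flagged), `n_shared_columns` (integer matrix of columns used
#'   per pair).
#' @export
jaccard_matrix <- function(m) {
  stopifnot(inherits(m, "allele_matrix"))
  if (nrow(m$scores) < 2L) stop("need at least two samples")
  m <- block_normalize(m)
  ids <- sample_ids(m)
  P <- m$scores
  S <- !is.na(P)                 # scored indicator
  P[!S] <- 0L
  storage.mode(P) <- "double"
  storage.mode(S) <- "double"
  A <- S - P                     # scored and absent
  a <- tcrossprod(P)             # both present (missing already 0)
  b <- tcrossprod(P, A)          # present in row sample, absent in col
  un <- a + b + t(b)
  d <- 1 - a / un                # NaN where union empty
  d[un == 0] <- NA_real_
  diag(d) <- 0
  nsh <- tcrossprod(S)
  dimnames(d) <- dimnames(nsh) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 n_shared_columns = matrix(as.integer(nsh), nrow(nsh),
                                           dimnames = dimnames(nsh))),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> ", length(x$ids), " samples; ",
      sum(is.na(x$d[upper.tri(x$d)])), " undefined pair(s)\n", sep = "")
  invisible(x)
}

#' Similarity matrix
#'
#' Elementwise `1 - d`; undefined distances stay undefined.  95% similarity
#' (`d = 0.05`) is the conventional genebank redundancy boundary.
#'
#' @param dm a `dist_matrix` from [jaccard_matrix()].
#' @return numeric matrix of similarities in `[0, 1]`.
#' @export
similarity <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  1 - dm$d
}

#' Write a distance matrix
#'
#' Two plain-text forms: `"square"` (header + square grid) and `"long"`
#' (`id1,id2,d,n_cols`, upper triangle only).
#'
#' @param dm a `dist_matrix`.
#' @param path file path.
#' @param format `"square"` or `"long"`.
#' @return invisibly, `path`.
#' @export
write_distances <- function(dm, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  } else {
    ut <- which(upper.tri(dm$d), arr.ind = TRUE)
    df <- data.frame(id1 = dm$ids[ut[, 1L]], id2 = dm$ids[ut[, 2L]],
                     d = dm$d[ut],
                     n_cols = dm$n_shared_columns[ut])
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# Coerce to stats::dist (used to interoperate with hclust etc.);
# undefined entries propagate as NA.
as_dist <- function(dm) stats::as.dist(dm$d)
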