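#' Paired true-to-type verification
#'
#' Compares the fingerprints of paired samples of the same accession
#' (typically a greenhouse mother plant and its in-vitro culture).  For
#' each pair, allele presence calls are compared over the columns of
#' markers scored in both samples; a pair is true-to-type (`TTT_match`)
#' when the number of mismatching calls is at most `tolerance`, not
#' true-to-type (`nTTT_mismatch`) otherwise, and `indeterminate` when
#' fewer than `min_loci` markers were co-scored.  Indeterminate pairs are
#' excluded from the mismatch percentage, so scoring dropouts do not
#' inflate the apparent error rate.
#'
#' @param m an [allele_matrix()] containing both members of every pair.
#' @param pairs two-column data.frame (or matrix) of sample ids.
#' @param tolerance maximum number of mismatching allele calls still
#'   counted as a match (default 0: any differing band is a mismatch).
#' @param min_loci minimum number of co-scored markers for a determinate
#'   verdict (default 1).
#' @return list of class `pair_verdicts`: `verdicts` (data.frame
#'   `sample_a`, `sample_b`, `accession_id`, `n_loci_compared`,
#'   `n_allele_mismatches`, `verdict`), `per_marker` (data.frame
#'   `sample_a`, `sample_b`, `marker`, `n_mismatches` for mismatching
#'   markers), `summary` (n_pairs, n_match, n_mismatch, n_indeterminate,
#'   percent_mismatch over determinate pairs).
#' @export
verify_pairs <- function(m, pairs, tolerance = 0L, min_loci = 1L) {
  stopifnot(inherits(m, "allele_matrix"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("`pairs` needs two sample-id columns")
  ids <- sample_ids(m)
  missing <- setdiff(unique(c(pairs[[1L]], pairs[[2L]])), ids)
  if (length(missing)) {
    stop("pair member(s) absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  m <- block_normalize(m)
  sb <- scored_blocks(m)
  blocks <- marker_blocks(m$panel)
  markers <- names(blocks)

  n <- nrow(pairs)
  res <- data.frame(sample_a = pairs[[1L]], sample_b = pairs[[2L]],
                    accession_id = parse_sample_ids(pairs[[1L]])$accession_id,
                    n_loci_compared = integer(n),
                    n_allele_mismatches = integer(n),
                    verdict = character(n), stringsAsFactors = FALSE)
  detail <- list()
  for (i in seq_len(n)) {
    a <- pairs[[1L]][i]; b <- pairs[[2L]][i]
    co <- markers[sb[a, ] & sb[b, ]]
    res$n_loci_compared[i] <- length(co)
    if (length(co) < min_loci) {
      res$verdict[i] <- "indeterminate"
      res$n_allele_mismatches[i] <- NA_integer_
      next
    }
    mm_total <- 0L
    for (mk in co) {
      idx <- blocks[[mk]]
      mm <- sum(m$scores[a, idx] != m$scores[b, idx])
      if (mm > 0L) {
        detail[[length(detail) + 1L]] <- data.frame(
          sample_a = a, sample_b = b, marker = mk, n_mismatches = mm,
          stringsAsFactors = FALSE)
      }
      mm_total <- mm_total + mm
    }
    res$n_allele_mismatches[i] <- mm_total
    res$verdict[i] <- if (mm_total <= tolerance) "TTT_match" else
      "nTTT_mismatch"
  }
  det <- sum(res$verdict != "indeterminate")
  n_mm <- sum(res$verdict == "nTTT_mismatch")
  structure(list(
    verdicts = res,
    per_marker = if (length(detail)) do.call(rbind, detail) else
      data.frame(sample_a = character(0), sample_b = character(0),
                 marker = character(0), n_mismatches = integer(0),
                 stringsAsFactors = FALSE),
    summary = list(n_pairs = n, n_match = sum(res$verdict == "TTT_match"),
                   n_mismatch = n_mm,
                   n_indeterminate = n - det,
                   percent_mismatch = if (det > 0) 100 * n_mm / det else
                     NA_real_)),
    class = "pair_verdicts")
}

#' @export
print.pair_verdicts <- function(x, ...) {
  s <- x$summary
  cat("<pair_verdicts> ", s$n_pairs, " pairs: ", s$n_match, " match, ",
      s$n_mismatch, " mismatch (",
      format(s$percent_mismatch, digits = 3), "%), ",
      s$n_indeterminate, " indeterminate\n", sep = "")
  invisible(x)
}

# Similarity of every query sample to every reference sample, computed on
# the merged (panel-aligned) matrix.  Returns query x reference matrix.
cross_similarity <- function(query, reference) {
  merged <- merge_matrices(query, reference,
                           labels = c("query", "reference"))
  qids <- sample_ids(query)
  rids <- sample_ids(reference)
  mids <- sample_ids(merged)
  q_m <- mids[seq_along(qids)]
  r_m <- mids[length(qids) + seq_along(rids)]
  s <- similarity(jaccard_matrix(merged))
  out <- s[q_m, r_m, drop = FALSE]
  dimnames(out) <- list(qids, rids)
  out
}

#' Cross-collection reconciliation
#'
#' Classifies every query sample against a reference collection, the
#' exercise of checking whether materials exchanged between genebanks are
#' still what their labels claim.  Declared transfers (documented
#' exchanges) are checked against their declared counterpart; undeclared
#' name matches (same cultivar name acquired independently) are checked
#' the same way; all remaining queries are declared `unique` when no
#' reference sample reaches the uniqueness threshold, and `unlinked_hit`
#' (best hit reported) otherwise.
#'
#' @param query,reference [allele_matrix()] objects with the same marker
#'   name set (allele inventories may differ; see [merge_matrices()]).
#' @param links optional data.frame `query_id`, `reference_id`,
#'   `link_type` (`"declared_transfer"` or `"name_match"`); at most one
#'   link per query sample.
#' @param match_threshold similarity at or above which a linked counterpart
#'   is confirmed (default 1.0: identical fingerprints).
#' @param uniqueness_threshold similarity below which (against every
#'   reference) an unlinked query is unique (default 0.95, the redundancy
#'   convention).
#' @return list of class `reconciliation_report`: `report` (data.frame
#'   `query_id`, `category`, `linked_reference`, `link_similarity`,
#'   `best_hit`, `best_similarity`), `counts` (named integer per
#'   category), `thresholds`.
#' @export
reconcile <- function(query, reference, links = NULL,
                      match_threshold = 1.0, uniqueness_threshold = 0.95) {
  s <- cross_similarity(query, reference)
  qids <- rownames(s)
  rids <- colnames(s)

  link_of <- stats::setNames(rep(NA_character_, length(qids)), qids)
  type_of <- link_of
  if (!is.null(links) && nrow(links)) {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    need <- c("query_id", "reference_id", "link_type")
    if (!all(need %in% names(links))) {
      stop("links must have columns ", paste(need, collapse = ", "))
    }
    bad <- setdiff(links$query_id, qids)
    if (length(bad)) stop("link references unknown query sample(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    bad <- setdiff(links$reference_id, rids)
    if (length(bad)) stop("link references unknown reference sample(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    bad <- !links$link_type %in% c("declared_transfer", "name_match")
    if (any(bad)) stop("unknown link_type: ",
                       paste(unique(links$link_type[bad]), collapse = ", "))
    if (anyDuplicated(links$query_id)) {
      stop("multiple links for query sample(s): ",
           paste(unique(links$query_id[duplicated(links$query_id)]),
                 collapse = ", "))
    }
    link_of[links$query_id] <- links$reference_id
    type_of[links$query_id] <- links$link_type
  }

  best_idx <- apply(s, 1L, function(v) {
    if (all(is.na(v))) NA_integer_ else which.max(v)
  })
  best_hit <- ifelse(is.na(best_idx), NA_character_, rids[best_idx])
  best_sim <- vapply(seq_along(qids), function(i) {
    if (is.na(best_idx[i])) NA_real_ else s[i, best_idx[i]]
  }, numeric(1))

  category <- character(length(qids))
  link_sim <- rep(NA_real_, length(qids))
  for (i in seq_along(qids)) {
    q <- qids[i]
    if (!is.na(link_of[q])) {
      link_sim[i] <- s[q, link_of[q]]
      hit <- !is.na(link_sim[i]) && link_sim[i] >= match_threshold
      category[i] <- switch(type_of[q],
        declared_transfer = if (hit) "shared_match" else "shared_mismatch",
        name_match = if (hit) "name_match_genotype_match" else
          "name_match_genotype_mismatch")
    } else {
      category[i] <- if (is.na(best_sim[i]) ||
                         best_sim[i] < uniqueness_threshold) "unique" else
        "unlinked_hit"
    }
  }

  levs <- c("shared_match", "shared_mismatch", "name_match_genotype_match",
            "name_match_genotype_mismatch", "unique", "unlinked_hit")
  report <- data.frame(query_id = qids, category = category,
                       linked_reference = unname(link_of),
                       link_similarity = link_sim,
                       best_hit = best_hit, best_similarity = best_sim,
                       stringsAsFactors = FALSE)
  counts <- table(factor(category, levels = levs))
  structure(list(report = report,
                 counts = stats::setNames(as.integer(counts), levs),
                 thresholds = list(match = match_threshold,
                                   uniqueness = uniqueness_threshold)),
            class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat("<reconciliation_report> ", nrow(x$report), " query samples\n",
      sep = "")
  for (k in names(x$counts)) {
    if (x$counts[[k]] > 0L) cat("  ", k, ": ", x$counts[[k]], "\n", sep = "")
  }
  invisible(x)
}

#' Nearest reference neighbors of query samples
#'
#' Ranks, for every query sample, the `k` most similar reference samples,
#' and reports the union of all reference ids appearing in any top-k list
#' (the "most similar" reference subset used when building a joint tree of
#' two collections).  Ties are broken by reference column order.
#'
#' @param query,reference [allele_matrix()] objects with matching marker
#'   name sets.
#' @param k number of neighbors per query (capped at the reference size).
#' @return list: `hits` (data.frame `query_id`, `rank`, `reference_id`,
#'   `similarity`), `reference_union` (character).
#' @export
nearest_neighbors <- function(query, reference, k = 1L) {
  stopifnot(k >= 1L)
  s <- cross_similarity(query, reference)
  k <- min(k, ncol(s))
  hits <- lapply(rownames(s), function(q) {
    v <- s[q, ]
    ord <- order(-v, seq_along(v))[seq_len(k)]
    data.frame(query_id = q, rank = seq_len(k),
               reference_id = colnames(s)[ord],
               similarity = unname(v[ord]), stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  list(hits = hits, reference_union = sort(unique(hits$reference_id)))
}
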