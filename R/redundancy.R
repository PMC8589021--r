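#' Find putative duplicate groups at a similarity threshold
#'
#' Groups samples whose pairwise Jaccard similarity (`1 - d`) reaches the
#' threshold.  Under `"single"` linkage (default) groups are the connected
#' components of the threshold graph: a chain A~B~C is one group even if A
#' and C fall below the threshold — the weakest assumption consistent with
#' "remove all but one of each similar set".  Under `"complete"` linkage
#' groups are cut from a complete-linkage dendrogram at `1 - threshold`,
#' so every within-group pair meets the threshold (cliques).  Pairs with
#' undefined distance never merge groups.
#'
#' The representative of each group is its lexicographically smallest
#' sample id, making the pruned set independent of input row order.
#'
#' @param dm a `dist_matrix` from [jaccard_matrix()].
#' @param threshold similarity threshold in (0, 1]; 0.95 is the
#'   conventional genebank redundancy boundary.
#' @param linkage `"single"` or `"complete"`.
#' @return object of class `duplicate_groups`: list with `threshold`,
#'   `linkage`, `groups` (list of character vectors, each sorted),
#'   `representative` (character, one per group), `pruned_ids` (sorted
#'   representatives), `n_undefined_pairs`.
#' @export
find_duplicates <- function(dm, threshold = 0.95,
                            linkage = c("single", "complete")) {
  stopifnot(inherits(dm, "dist_matrix"))
  linkage <- match.arg(linkage)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]")
  }
  ids <- dm$ids
  n <- length(ids)
  s <- 1 - dm$d
  n_undef <- sum(is.na(s[upper.tri(s)]))

  if (linkage == "single") {
    # union-find over edges with similarity >= threshold
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    hit <- which(!is.na(s) & s >= threshold & upper.tri(s), arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      a <- find(hit[r, 1L]); b <- find(hit[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    comp <- vapply(seq_len(n), find, integer(1))
  } else {
    d <- dm$d
    d[is.na(d)] <- 2           # undefined pairs can never co-cluster
    if (n == 1L) {
      comp <- 1L
    } else {
      hc <- stats::hclust(stats::as.dist(d), method = "complete")
      comp <- stats::cutree(hc, h = 1 - threshold)
    }
  }

  groups <- split(ids, comp)
  groups <- lapply(groups, sort)
  reps <- vapply(groups, `[`, character(1), 1L)
  ord <- order(reps)
  groups <- unname(groups[ord])
  reps <- unname(reps[ord])
  structure(list(threshold = threshold, linkage = linkage,
                 groups = groups, representative = reps,
                 pruned_ids = reps, n_undefined_pairs = n_undef),
            class = "duplicate_groups")
}

#' @export
print.duplicate_groups <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat("<duplicate_groups> ", sum(sizes), " samples -> ", length(x$groups),
      " groups at similarity >= ", x$threshold, " (", x$linkage,
      " linkage); largest group ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Prune a collection to duplicate-group representatives
#'
#' @param m the [allele_matrix()] the groups were computed from.
#' @param groups a `duplicate_groups` from [find_duplicates()].
#' @return list: `matrix` (pruned [allele_matrix()], rows in original
#'   order), `n_removed`, `percent_removed`, `removed_ids`.
#' @export
prune_duplicates <- function(m, groups) {
  stopifnot(inherits(m, "allele_matrix"),
            inherits(groups, "duplicate_groups"))
  ids <- sample_ids(m)
  covered <- unlist(groups$groups, use.names = FALSE)
  if (!setequal(covered, ids)) {
    stop("duplicate groups do not match the matrix sample ids ",
         "(stale groups?)")
  }
  keep <- ids[ids %in% groups$pruned_ids]   # original row order
  removed <- setdiff(ids, keep)
  list(matrix = subset_matrix(m, keep),
       n_removed = length(removed),
       percent_removed = 100 * length(removed) / length(ids),
       removed_ids = removed)
}

#' Histogram of pairwise distances
#'
#' The redundancy profile of a collection: binned counts of all pairwise
#' distances over `[0, 1]`, plus the count and fraction of pairs at or
#' above a similarity threshold.
#'
#' @param dm a `dist_matrix`.
#' @param bins number of equal-width bins over `[0, 1]`.
#' @param threshold similarity threshold for the tail summary.
#' @return list: `histogram` (data.frame `lower`, `upper`, `count`),
#'   `n_pairs`, `n_undefined`, `n_at_threshold`, `fraction_at_threshold`.
#' @export
similarity_distribution <- function(dm, bins = 20L, threshold = 0.95) {
  stopifnot(inherits(dm, "dist_matrix"), bins >= 1L)
  d <- dm$d[upper.tri(dm$d)]
  if (!length(d)) stop("need at least one pair")
  ok <- !is.na(d)
  br <- seq(0, 1, length.out = bins + 1L)
  cnt <- table(cut(d[ok], breaks = br, include.lowest = TRUE,
                   right = FALSE))
  # cut(right = FALSE) puts d == 1 out of range unless include.lowest;
  # include.lowest with right = FALSE closes the last interval
  hist <- data.frame(lower = br[-length(br)], upper = br[-1L],
                     count = as.integer(cnt))
  nat <- sum(ok & (1 - d) >= threshold, na.rm = TRUE)
  list(histogram = hist, n_pairs = length(d), n_undefined = sum(!ok),
       n_at_threshold = nat,
       fraction_at_threshold = nat / length(d))
}
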