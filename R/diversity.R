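#' Per-marker allele counts
#'
#' For every marker: the number of alleles observed present in at least one
#' scored sample, and the mean number of alleles carried per individual
#' (averaged over samples whose marker block is scored).  These are the two
#' inventory statistics genebank fingerprinting reports tabulate per
#' marker.
#'
#' @param m an [allele_matrix()] (partially scored blocks are treated as
#'   missing).
#' @return data.frame with columns `marker`, `n_scored`,
#'   `total_alleles`, `mean_alleles_per_individual` (NA when
#'   `n_scored == 0`, flagged in column `undefined`).
#' @export
allele_counts <- function(m) {
  stopifnot(inherits(m, "allele_matrix"))
  if (nrow(m$scores) < 1L) stop("allele_counts needs at least one sample")
  m <- block_normalize(m)
  blocks <- marker_blocks(m$panel)
  out <- lapply(names(blocks), function(mk) {
    blk <- m$scores[, blocks[[mk]], drop = FALSE]
    scored <- rowSums(is.na(blk)) == 0L
    ns <- sum(scored)
    if (ns == 0L) {
      return(data.frame(marker = mk, n_scored = 0L, total_alleles = 0L,
                        mean_alleles_per_individual = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    sb <- blk[scored, , drop = FALSE]
    data.frame(marker = mk, n_scored = ns,
               total_alleles = sum(colSums(sb) > 0L),
               mean_alleles_per_individual = mean(rowSums(sb)),
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Equal-dosage allele frequencies from dominant scores
#'
#' In a dominant-scored polyploid, dosage is unobservable: a sample
#' presenting k distinct alleles at a marker could carry them in any copy
#' configuration summing to the ploidy.  The equal-dosage estimator gives
#' each presented allele weight 1/k, and averages those weights over the
#' scored samples of a group, so per-marker frequencies sum to one.
#'
#' Samples with a missing block at a marker are excluded from that marker
#' only (pairwise-complete).  A scored block presenting zero alleles (a
#' null fingerprint) carries no frequency information and is likewise
#' excluded from that marker, with a flag.
#'
#' @param m an [allele_matrix()].
#' @param groups optional named character vector or factor mapping sample
#'   ids to group labels; unmapped samples are dropped.  `NULL` puts every
#'   sample in one group `"all"`.
#' @return data.frame of class `allele_freqs` with columns `group`,
#'   `marker`, `allele`, `freq`, `n_scored` (samples contributing to that
#'   (group, marker)).  (group, marker) combinations with `n_scored == 0`
#'   are present with `freq = NA`.
#' @export
allele_frequencies <- function(m, groups = NULL) {
  stopifnot(inherits(m, "allele_matrix"))
  m <- block_normalize(m)
  ids <- sample_ids(m)
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(ids)), ids)
  }
  groups <- stats::setNames(as.character(groups), names(groups))
  groups <- groups[names(groups) %in% ids]
  blocks <- marker_blocks(m$panel)
  out <- list()
  for (g in unique(groups)) {
    gids <- names(groups)[groups == g]
    sub <- m$scores[gids, , drop = FALSE]
    for (mk in names(blocks)) {
      blk <- sub[, blocks[[mk]], drop = FALSE]
      k <- rowSums(blk)                       # NA when block missing
      use <- !is.na(k) & k > 0L
      ns <- sum(use)
      alle <- m$panel$alleles[[mk]]
      if (ns == 0L) {
        fr <- rep(NA_real_, length(alle))
      } else {
        w <- blk[use, , drop = FALSE] / k[use]    # 1/k per presented allele
        fr <- colSums(w) / ns
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, marker = mk, allele = alle, freq = unname(fr),
        n_scored = ns, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("allele_freqs", "data.frame")
  res
}

#' Polymorphism information content (PIC)
#'
#' Botstein's marker informativeness statistic,
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,}
#' computed per marker (and per group) from an allele frequency table.
#'
#' @param freqs an `allele_freqs` table from [allele_frequencies()].
#' @return data.frame with columns `group`, `marker`, `pic` (`NA` where
#'   frequencies are undefined).
#' @export
pic <- function(freqs) {
  per_marker_stat(freqs, function(p) {
    s2 <- sum(p^2)
    # double sum over unordered pairs: ((sum p^2)^2 - sum p^4) expands
    # 2 * sum_{i<j} p_i^2 p_j^2
    1 - s2 - (s2^2 - sum(p^4))
  }, "pic")
}

#' Expected heterozygosity
#'
#' Nei's gene diversity \eqn{H_e = 1 - \sum_i p_i^2} per marker, plus the
#' unweighted mean over markers per group (the collection-level summary
#' usually reported).
#'
#' @param freqs an `allele_freqs` table from [allele_frequencies()].
#' @return list with `per_marker` (data.frame `group`, `marker`, `He`) and
#'   `mean` (named numeric, one value per group; NA markers dropped).
#' @export
expected_heterozygosity <- function(freqs) {
  per <- per_marker_stat(freqs, function(p) 1 - sum(p^2), "He")
  means <- tapply(per$He, per$group, function(v) mean(v, na.rm = TRUE))
  list(per_marker = per, mean = c(means))
}

per_marker_stat <- function(freqs, f, name) {
  stopifnot(is.data.frame(freqs),
            all(c("group", "marker", "allele", "freq") %in% names(freqs)))
  key <- interaction(freqs$group, freqs$marker, drop = TRUE, sep = "\r")
  vals <- tapply(freqs$freq, key, function(p) {
    if (anyNA(p)) NA_real_ else f(p[p > 0])
  })
  parts <- do.call(rbind, strsplit(names(vals), "\r", fixed = TRUE))
  out <- data.frame(group = parts[, 1L], marker = parts[, 2L],
                    stat = as.numeric(vals), stringsAsFactors = FALSE)
  names(out)[3L] <- name
  rownames(out) <- NULL
  out[order(match(out$group, unique(freqs$group)),
            match(out$marker, unique(freqs$marker))), , drop = FALSE]
}

#' Fst from group allele frequencies
#'
#' Per marker: within-group gene diversity \eqn{H_{s,g} = 1 - \sum_i
#' p_{g,i}^2}, total diversity \eqn{H_t} from pooled frequencies (groups
#' weighted by their number of scored samples), and
#' \eqn{F_{st} = (H_t - \bar{H_s}) / H_t} with \eqn{\bar{H_s}} the
#' scored-sample-weighted mean of the \eqn{H_{s,g}}.  The summary over
#' markers is the \eqn{H_t}-weighted mean, i.e. the ratio of sums
#' \eqn{\sum_m (H_{t,m} - \bar{H}_{s,m}) / \sum_m H_{t,m}}.  Sampling
#' noise can push an estimate below zero; such values are clamped to 0 and
#' flagged.
#'
#' @param m an [allele_matrix()].
#' @param groups named character vector/factor mapping sample ids to group
#'   labels; at least two groups must have scored samples.
#' @return list of class `fst_result`: `fst` (summary scalar),
#'   `Ht` (weighted mean total diversity), `mean_Hs`, `per_marker`
#'   (data.frame `marker`, `Ht`, `mean_Hs`, `fst`, `clamped`),
#'   `clamped` (logical, any marker clamped), `grouping` (group sizes).
#' @export
fst <- function(m, groups) {
  stopifnot(inherits(m, "allele_matrix"))
  if (is.null(groups)) stop("fst needs a grouping")
  fr <- allele_frequencies(m, groups)
  glab <- unique(fr$group)
  if (length(glab) < 2L) stop("fst needs >= 2 groups with samples")
  per <- list()
  for (mk in unique(fr$marker)) {
    sub <- fr[fr$marker == mk, , drop = FALSE]
    sub <- sub[!is.na(sub$freq), , drop = FALSE]
    gs <- unique(sub$group)
    if (length(gs) < 2L) next           # marker unusable for differentiation
    # group weights: number of scored samples
    wts <- vapply(gs, function(g) sub$n_scored[sub$group == g][1L], numeric(1))
    Hs <- vapply(gs, function(g) {
      p <- sub$freq[sub$group == g]
      1 - sum(p^2)
    }, numeric(1))
    mean_Hs <- sum(wts * Hs) / sum(wts)
    # pooled frequencies, weighted by scored sample counts
    alle <- unique(sub$allele)
    pool <- vapply(alle, function(a) {
      rows <- sub$allele == a
      sum(sub$freq[rows] * wts[match(sub$group[rows], gs)]) / sum(wts)
    }, numeric(1))
    Ht <- 1 - sum(pool^2)
    f <- if (Ht > 0) (Ht - mean_Hs) / Ht else NA_real_
    clamped <- isTRUE(f < 0)
    if (clamped) f <- 0
    per[[length(per) + 1L]] <- data.frame(
      marker = mk, Ht = Ht, mean_Hs = mean_Hs, fst = f,
      clamped = clamped, stringsAsFactors = FALSE)
  }
  if (!length(per)) stop("no marker is scored in >= 2 groups")
  per <- do.call(rbind, per)
  ok <- !is.na(per$fst) & per$Ht > 0
  summary_fst <- sum(per$Ht[ok] * per$fst[ok]) / sum(per$Ht[ok])
  clamped <- summary_fst < 0
  if (clamped) summary_fst <- 0
  sizes <- table(as.character(groups))
  out <- list(fst = summary_fst,
              Ht = stats::weighted.mean(per$Ht[ok], per$Ht[ok]),
              mean_Hs = stats::weighted.mean(per$mean_Hs[ok], per$Ht[ok]),
              per_marker = per,
              clamped = clamped || any(per$clamped),
              grouping = sizes)
  class(out) <- "fst_result"
  out
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> Fst = ", format(x$fst, digits = 4),
      " over ", nrow(x$per_marker), " markers, ",
      length(x$grouping), " groups",
      if (x$clamped) " (some estimates clamped at 0)", "\n", sep = "")
  invisible(x)
}

#' Per-marker diversity report
#'
#' Convenience wrapper producing the standard fingerprinting summary table
#' (one row per marker: total alleles, mean alleles per individual, PIC,
#' expected heterozygosity), the shape in which such panels are published.
#'
#' @param m an [allele_matrix()].
#' @param path optional file path; when given the table is also written as
#'   CSV.
#' @return data.frame with columns `marker`, `n_scored`, `total_alleles`,
#'   `mean_alleles_per_individual`, `pic`, `He`.
#' @export
diversity_report <- function(m, path = NULL) {
  ac <- allele_counts(m)
  fr <- allele_frequencies(m)
  p <- pic(fr)
  he <- expected_heterozygosity(fr)$per_marker
  out <- data.frame(marker = ac$marker, n_scored = ac$n_scored,
                    total_alleles = ac$total_alleles,
                    mean_alleles_per_individual =
                      ac$mean_alleles_per_individual,
                    pic = p$pic[match(ac$marker, p$marker)],
                    He = he$He[match(ac$marker, he$marker)],
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Summarise a published marker panel table
#'
#' Column-wise summaries of a per-marker statistics table (as produced by
#' [diversity_report()] or entered from a publication): means of total
#' allele counts and PIC, their ranges, and the range of mean alleles per
#' individual.
#'
#' @param tab data.frame with columns `total_alleles`, `pic` and optionally
#'   `mean_alleles_per_individual`.
#' @return named list of summary numbers.
#' @export
summarise_marker_table <- function(tab) {
  stopifnot(all(c("total_alleles", "pic") %in% names(tab)))
  out <- list(
    n_markers = nrow(tab),
    mean_total_alleles = mean(tab$total_alleles),
    min_total_alleles = min(tab$total_alleles),
    max_total_alleles = max(tab$total_alleles),
    mean_pic = mean(tab$pic),
    min_pic = min(tab$pic),
    max_pic = max(tab$pic)
  )
  if ("mean_alleles_per_individual" %in% names(tab)) {
    out$min_mean_alleles_per_individual <-
      min(tab$mean_alleles_per_individual)
    out$max_mean_alleles_per_individual <-
      max(tab$mean_alleles_per_individual)
  }
  out
}

#' The published CIP sweetpotato 20-marker panel summary
#'
#' The per-marker summary of the 20-SSR panel used to fingerprint the CIP
#' sweetpotato collection (marker, allele size range, total alleles, mean
#' alleles per individual, PIC on the full collection, PIC on the USDA
#' subset, motif), shipped as a packaged fixture for desk-scale checks of
#' the report tooling.
#'
#' @return data.frame with one row per marker.
#' @export
cip_marker_summary <- function() {
  path <- system.file("extdata", "cip_sweetpotato_marker_summary.csv",
                      package = "ssrkit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(marker = "character", motif = "character"))
}
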