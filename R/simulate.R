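#' Configuration of the hexaploid fingerprint simulator
#'
#' Parameterizes [simulate_collection()].  The generative model: per
#' marker a base allele-frequency vector is drawn from a symmetric
#' Dirichlet with concentration `dirichlet_concentration`; each of the `K`
#' ancestral populations perturbs it with a Balding-Nichols-style
#' Dirichlet draw whose precision is set by `divergence` (which is,
#' in expectation, the Fst between populations); individuals draw ancestry
#' proportions from `Dirichlet(admixture_alpha)`, then `ploidy` allele
#' copies per marker from their ancestry-mixed frequencies, collapsed to
#' presence/absence (dominant scoring).  Noise processes: clonal
#' duplication, per-allele-call flips, whole-block missingness, and (for
#' paired fixtures) label swaps that replace a sample's fingerprint with
#' another individual's at rate `label_swap_rate`.
#'
#' Defaults emulate a hexaploid genebank collection fingerprinted with a
#' 20-SSR panel: 15 alleles per marker, four ancestral populations with
#' weak differentiation and little admixture, a 2% block-dropout rate, and
#' no scoring errors or label swaps unless requested.  Under these
#' defaults, per-marker mean alleles per individual falls in the 2-4 band
#' observed for real hexaploid sweetpotato panels.
#'
#' @param n_markers number of SSR markers.
#' @param alleles_per_marker scalar or per-marker integer vector.
#' @param K number of ancestral populations.
#' @param dirichlet_concentration symmetric Dirichlet concentration of the
#'   base frequency spectrum (smaller = sharper spectra, fewer effective
#'   alleles).
#' @param divergence between-population differentiation in `[0, 1)`;
#'   populations draw from `Dirichlet(q (1 - d) / d)` around base
#'   frequencies `q`, so expected Fst is about `d`.  0 = panmixia.
#' @param admixture_alpha per-individual ancestry Dirichlet concentration
#'   (small = most individuals nearly pure).
#' @param ploidy allele copies drawn per marker (6 = hexaploid).
#' @param n_individuals number of distinct founder individuals.
#' @param clone_rate probability an individual is emitted with extra
#'   clonal copies.
#' @param clone_copy_distribution probabilities over the number of extra
#'   copies (1, 2, ...).
#' @param missing_rate per-(sample, marker)-block dropout probability.
#' @param scoring_error_rate per-allele-call flip probability.
#' @param label_swap_rate probability a paired sample is emitted with a
#'   different individual's fingerprint.
#' @param seed integer RNG seed; identical config + seed gives
#'   bit-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 20L, alleles_per_marker = 15L, K = 4L,
                       dirichlet_concentration = 0.25, divergence = 0.02,
                       admixture_alpha = 0.3, ploidy = 6L,
                       n_individuals = 100L, clone_rate = 0,
                       clone_copy_distribution = 1, missing_rate = 0.02,
                       scoring_error_rate = 0, label_swap_rate = 0,
                       seed = 1L) {
  cfg <- list(n_markers = as.integer(n_markers),
              alleles_per_marker = as.integer(alleles_per_marker),
              K = as.integer(K),
              dirichlet_concentration = dirichlet_concentration,
              divergence = divergence,
              admixture_alpha = admixture_alpha,
              ploidy = as.integer(ploidy),
              n_individuals = as.integer(n_individuals),
              clone_rate = clone_rate,
              clone_copy_distribution = clone_copy_distribution,
              missing_rate = missing_rate,
              scoring_error_rate = scoring_error_rate,
              label_swap_rate = label_swap_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_markers < 1L) stop("n_markers must be >= 1")
    if (!(length(alleles_per_marker) %in% c(1L, n_markers))) {
      stop("alleles_per_marker must be scalar or length n_markers")
    }
    if (K < 1L) stop("K must be >= 1")
    if (ploidy < 2L) stop("ploidy must be >= 2")
    if (n_individuals < 1L) stop("n_individuals must be >= 1")
    if (dirichlet_concentration <= 0) {
      stop("dirichlet_concentration must be positive")
    }
    if (admixture_alpha <= 0) stop("admixture_alpha must be positive")
    if (divergence < 0 || divergence >= 1) {
      stop("divergence must be in [0, 1)")
    }
    for (p in c("clone_rate", "missing_rate", "scoring_error_rate",
                "label_swap_rate")) {
      v <- cfg[[p]]
      if (v < 0 || v > 1) stop(p, " must be in [0, 1]")
    }
    if (any(clone_copy_distribution < 0) ||
        abs(sum(clone_copy_distribution) - 1) > 1e-9) {
      stop("clone_copy_distribution must be probabilities summing to 1")
    }
    if (divergence > 0 && any(alleles_per_marker < 2L)) {
      stop("population divergence requires >= 2 alleles per marker")
    }
  })
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1   # degenerate guard
  x / sum(x)
}

# Draw base and per-population allele frequencies for every marker.
draw_population_freqs <- function(cfg) {
  A <- rep_len(cfg$alleles_per_marker, cfg$n_markers)
  lapply(seq_len(cfg$n_markers), function(mi) {
    q <- rdirichlet1(rep(cfg$dirichlet_concentration, A[mi]))
    if (cfg$divergence > 0 && cfg$K > 1L) {
      tau <- (1 - cfg$divergence) / cfg$divergence
      p <- vapply(seq_len(cfg$K),
                  function(g) rdirichlet1(q * tau + 1e-12),
                  numeric(A[mi]))
    } else {
      p <- matrix(q, nrow = A[mi], ncol = cfg$K)
    }
    list(base = q, pop = p)   # pop: alleles x K
  })
}

# Dominant fingerprint of one individual: ploidy multinomial draws from
# ancestry-mixed frequencies, collapsed to presence/absence.
draw_fingerprint <- function(cfg, freqs, w) {
  unlist(lapply(freqs, function(f) {
    p <- as.vector(f$pop %*% w)
    counts <- stats::rmultinom(1L, cfg$ploidy, p)
    as.integer(counts > 0L)
  }), use.names = FALSE)
}

apply_noise <- function(row, cfg, block_idx) {
  if (cfg$scoring_error_rate > 0) {
    flip <- stats::runif(length(row)) < cfg$scoring_error_rate
    row[flip] <- 1L - row[flip]
  }
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(length(block_idx)) < cfg$missing_rate
    for (b in which(drop)) row[block_idx[[b]]] <- NA_integer_
  }
  row
}

sim_panel <- function(cfg) {
  A <- rep_len(cfg$alleles_per_marker, cfg$n_markers)
  markers <- sprintf("M%02d", seq_len(cfg$n_markers))
  # allele labels mimic fragment sizes: 3-bp ladder from a per-marker base
  alleles <- lapply(seq_len(cfg$n_markers), function(mi) {
    as.character(100L + 10L * mi + 3L * (seq_len(A[mi]) - 1L))
  })
  marker_panel(markers, alleles)
}

#' Simulate a dominant-scored polyploid SSR collection
#'
#' Runs the generative model described in [sim_config()] and returns the
#' scored matrix together with passport metadata and the complete ground
#' truth (population frequencies, ancestries, pre-noise fingerprints,
#' clone groups), enabling parameter-recovery tests of every downstream
#' analysis.
#'
#' Biological statuses in the passport table are assigned at the
#' proportions observed in a large clonal genebank collection (71%
#' landrace, 25% breeding line, 4% improved variety, 0.3% unclassified);
#' the pseudo-country records the individual's majority ancestral
#' population.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_result`: `matrix` ([allele_matrix()]),
#'   `passport` ([passport_table()]), `truth` (list: `samples` data.frame
#'   with `sample_id`, `individual`, `population`, `clone_group`,
#'   `ancestry` matrix, `fingerprints` pre-noise matrix, `freqs`
#'   per-marker frequency draws, `config`).
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panel <- sim_panel(cfg)
  freqs <- draw_population_freqs(cfg)
  n <- cfg$n_individuals

  W <- do.call(rbind, lapply(seq_len(n), function(i) {
    rdirichlet1(rep(cfg$admixture_alpha, cfg$K))
  }))
  fp <- t(vapply(seq_len(n), function(i) draw_fingerprint(cfg, freqs, W[i, ]),
                 integer(sum(lengths(panel$alleles)))))
  ind_ids <- sprintf("SIM%04d", seq_len(n))
  rownames(fp) <- ind_ids
  colnames(fp) <- panel_columns(panel)
  rownames(W) <- ind_ids

  # clonal duplication
  n_copies <- integer(n)
  if (cfg$clone_rate > 0) {
    dup <- stats::runif(n) < cfg$clone_rate
    cc <- seq_along(cfg$clone_copy_distribution)
    n_copies[dup] <- sample(cc, sum(dup), replace = TRUE,
                            prob = cfg$clone_copy_distribution)
  }
  samples <- data.frame(
    sample_id = c(ind_ids,
                  unlist(lapply(which(n_copies > 0L), function(i) {
                    sprintf("%s-d%d", ind_ids[i], seq_len(n_copies[i]))
                  }), use.names = FALSE)),
    individual = c(ind_ids,
                   rep(ind_ids, n_copies)),
    stringsAsFactors = FALSE)
  samples$population <- apply(W[samples$individual, , drop = FALSE], 1L,
                              which.max)
  samples$clone_group <- samples$individual

  block_idx <- marker_blocks(panel)
  scores <- fp[samples$individual, , drop = FALSE]
  rownames(scores) <- samples$sample_id
  for (i in seq_len(nrow(scores))) {
    scores[i, ] <- apply_noise(scores[i, ], cfg, block_idx)
  }
  m <- allele_matrix(scores, panel)

  status <- sample(c("landrace", "breeding_line", "improved_variety",
                     "unclassified"), nrow(samples), replace = TRUE,
                   prob = c(0.7117, 0.2459, 0.0395, 0.0030))
  pp <- passport_table(samples$sample_id,
                       name = samples$sample_id,
                       country = paste0("region_", samples$population),
                       biological_status = status,
                       collection = "SIM",
                       sample_source = "unspecified")

  structure(list(matrix = m, passport = pp,
                 truth = list(samples = samples, ancestry = W,
                              fingerprints = fp, freqs = freqs,
                              config = cfg)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", nrow(x$matrix$scores), " samples (",
      x$truth$config$n_individuals, " individuals), ",
      x$truth$config$n_markers, " markers, K = ", x$truth$config$K,
      "\n", sep = "")
  invisible(x)
}

# swap donor: a different individual whose fingerprint differs in >= 1
# allele call (so a swap is always detectable).
pick_swap_donor <- function(fp, owner) {
  others <- setdiff(rownames(fp), owner)
  others <- sample(others)
  for (o in others) {
    if (any(fp[o, ] != fp[owner, ])) return(o)
  }
  stop("no distinguishable swap donor exists (all fingerprints identical)")
}

#' Paired mother-plant / in-vitro fixture with planted label swaps
#'
#' Emits, for `n_pairs` simulated individuals, a `mother` and an
#' `invitro` sample.  With probability `label_swap_rate` (from `cfg`) the
#' in-vitro sample's fingerprint is replaced by a *different* individual's
#' complete fingerprint (germplasm mixing), guaranteed to differ in at
#' least one allele call so every swap is detectable by [verify_pairs()].
#'
#' @param cfg a [sim_config()]; `n_individuals` must be at least
#'   `n_pairs` (and at least 2 for swaps to have a donor).
#' @param n_pairs number of paired accessions to emit.
#' @return list of class `paired_fixture`: `matrix` (pairs only,
#'   `id|mother` / `id|invitro` rows), `pairs` (data.frame `accession_id`,
#'   `sample_a`, `sample_b`), `truth` (data.frame with `swapped` flag and
#'   `donor`), `n_swapped`, `sim` (the underlying `sim_result`).
#' @export
make_paired_fixture <- function(cfg, n_pairs) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_pairs > cfg$n_individuals) {
    stop("n_pairs exceeds n_individuals")
  }
  sim <- simulate_collection(cfg)
  fp <- sim$truth$fingerprints
  panel <- sim$matrix$panel
  block_idx <- marker_blocks(panel)
  acc <- rownames(fp)[seq_len(n_pairs)]

  swapped <- stats::runif(n_pairs) < cfg$label_swap_rate
  donor <- rep(NA_character_, n_pairs)
  rows <- list()
  rids <- character(0)
  for (i in seq_len(n_pairs)) {
    a <- acc[i]
    mother <- apply_noise(fp[a, ], cfg, block_idx)
    src <- a
    if (swapped[i]) {
      src <- pick_swap_donor(fp, a)
      donor[i] <- src
    }
    invitro <- apply_noise(fp[src, ], cfg, block_idx)
    rows[[length(rows) + 1L]] <- mother
    rows[[length(rows) + 1L]] <- invitro
    rids <- c(rids, paste0(a, "|mother"), paste0(a, "|invitro"))
  }
  scores <- do.call(rbind, rows)
  dimnames(scores) <- list(rids, panel_columns(panel))
  pairs <- data.frame(accession_id = acc,
                      sample_a = paste0(acc, "|mother"),
                      sample_b = paste0(acc, "|invitro"),
                      stringsAsFactors = FALSE)
  structure(list(matrix = allele_matrix(scores, panel), pairs = pairs,
                 truth = data.frame(accession_id = acc, swapped = swapped,
                                    donor = donor,
                                    stringsAsFactors = FALSE),
                 n_swapped = sum(swapped), sim = sim),
            class = "paired_fixture")
}

#' Two-collection fixture with planted link errors and unique queries
#'
#' Builds a reference collection and a query collection for
#' [reconcile()], with full ground truth: `n_shared` query samples are
#' exact clones of reference individuals with declared-transfer links, of
#' which `n_link_errors` links are re-pointed to a wrong reference
#' individual; `n_name_matches` further clones carry name-match links
#' (`n_name_match_errors` of them re-pointed); `n_unique_query` query
#' samples are new individuals verified to stay below the uniqueness
#' threshold against every reference sample.
#'
#' @param cfg a [sim_config()]; needs
#'   `n_individuals >= n_shared + n_name_matches + n_unique_query + 1`.
#' @param n_shared number of declared-transfer queries.
#' @param n_unique_query number of query-only individuals.
#' @param n_link_errors number of declared links pointed at wrong
#'   individuals.
#' @param n_name_matches,n_name_match_errors undeclared name-match queries
#'   and how many of them are wrong.
#' @param uniqueness_threshold the similarity bound enforced for unique
#'   queries (default 0.95).
#' @return list of class `two_collection_fixture`: `reference`, `query`
#'   ([allele_matrix()]s), `links` (data.frame `query_id`,
#'   `reference_id`, `link_type`), `truth` (data.frame `query_id`,
#'   `role`, `true_reference`), `sim`.
#' @export
make_two_collection_fixture <- function(cfg, n_shared, n_unique_query,
                                        n_link_errors,
                                        n_name_matches = 0L,
                                        n_name_match_errors = 0L,
                                        uniqueness_threshold = 0.95) {
  stopifnot(inherits(cfg, "sim_config"))
  n_linked <- n_shared + n_name_matches
  if (n_link_errors > n_shared) stop("n_link_errors exceeds n_shared")
  if (n_name_match_errors > n_name_matches) {
    stop("n_name_match_errors exceeds n_name_matches")
  }
  if (cfg$n_individuals < n_linked + 1L) {
    stop("need n_individuals >= n_shared + n_name_matches + 1")
  }
  sim <- simulate_collection(cfg)
  fp <- sim$truth$fingerprints
  panel <- sim$matrix$panel
  block_idx <- marker_blocks(panel)
  ref_ids <- rownames(fp)

  # reference: one sample per individual (noise applied)
  ref_scores <- fp
  for (i in seq_len(nrow(ref_scores))) {
    ref_scores[i, ] <- apply_noise(ref_scores[i, ], cfg, block_idx)
  }
  reference <- allele_matrix(ref_scores, panel)

  linked_ind <- ref_ids[seq_len(n_linked)]
  wrong <- c(seq_len(n_link_errors),
             if (n_name_match_errors > 0L)
               n_shared + seq_len(n_name_match_errors))
  q_rows <- list(); q_ids <- character(0)
  links <- data.frame(query_id = character(0), reference_id = character(0),
                      link_type = character(0), stringsAsFactors = FALSE)
  truth <- data.frame(query_id = character(0), role = character(0),
                      true_reference = character(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_linked)) {
    a <- linked_ind[i]
    qid <- paste0("Q-", a)
    q_rows[[length(q_rows) + 1L]] <- apply_noise(fp[a, ], cfg, block_idx)
    q_ids <- c(q_ids, qid)
    tgt <- a
    if (i %in% wrong) tgt <- pick_swap_donor(fp, a)
    links <- rbind(links, data.frame(
      query_id = qid, reference_id = tgt,
      link_type = if (i <= n_shared) "declared_transfer" else "name_match",
      stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      query_id = qid,
      role = if (i %in% wrong) "mislinked_clone" else "true_clone",
      true_reference = a, stringsAsFactors = FALSE))
  }

  # unique queries: fresh individuals kept below the uniqueness threshold
  # against every reference sample
  ref_sim_guard <- function(row) {
    probe <- rbind(ref_scores, UQ = row)
    s <- similarity(jaccard_matrix(allele_matrix(probe, panel)))
    max(s["UQ", ref_ids], na.rm = TRUE) < uniqueness_threshold
  }
  for (u in seq_len(n_unique_query)) {
    qid <- sprintf("Q-NEW%04d", u)
    for (try in 1:50) {
      w <- rdirichlet1(rep(cfg$admixture_alpha, cfg$K))
      row <- draw_fingerprint(cfg, sim$truth$freqs, w)
      names(row) <- panel_columns(panel)
      if (ref_sim_guard(row)) break
      if (try == 50L) stop("could not generate a sufficiently distinct ",
                           "unique query; lower the uniqueness threshold ",
                           "or enlarge the panel")
    }
    q_rows[[length(q_rows) + 1L]] <- apply_noise(row, cfg, block_idx)
    q_ids <- c(q_ids, qid)
    truth <- rbind(truth, data.frame(query_id = qid, role = "unique",
                                     true_reference = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  q_scores <- do.call(rbind, q_rows)
  dimnames(q_scores) <- list(q_ids, panel_columns(panel))
  structure(list(reference = reference,
                 query = allele_matrix(q_scores, panel),
                 links = links, truth = truth, sim = sim),
            class = "two_collection_fixture")
}

#' Read / write a simulation config as JSON
#'
#' @param path file path.
#' @return for `read_sim_config`, a [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
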