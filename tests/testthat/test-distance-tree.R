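test_that("jaccard_matrix matches hand-built pairs and ignores 0/0 columns", {
  alleles <- as.character(1:6)
  # a = 2 shared, b = 1, c = 1, plus a joint absence that must not count
  m <- one_marker_matrix(list(c("1", "2", "3"), c("1", "2", "4")), alleles)
  dm <- jaccard_matrix(m)
  expect_equal(dm$d[1, 2], 0.5)
  expect_equal(dm$d[2, 1], 0.5)
  expect_equal(diag(dm$d), c(S01 = 0, S02 = 0))

  ident <- one_marker_matrix(list(c("1", "3"), c("1", "3")), alleles)
  expect_equal(jaccard_matrix(ident)$d[1, 2], 0)

  disj <- one_marker_matrix(list(c("1", "2"), c("3", "4")), alleles)
  expect_equal(jaccard_matrix(disj)$d[1, 2], 1)
})

test_that("jaccard_matrix equals the brute-force set oracle with missing data", {
  set.seed(23)
  panel <- marker_panel(paste0("MK", 1:4),
                        alleles = rep(list(as.character(1:5)), 4))
  for (rep in 1:10) {
    m <- random_matrix(8, panel = panel, p_present = runif(1, 0.2, 0.6),
                       p_missing_block = 0.2)
    dm <- jaccard_matrix(m)
    cm <- panel_column_markers(panel)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(dm$d[i, j],
                   oracle_jaccard_pair(m$scores[i, ], m$scores[j, ], cm),
                   tolerance = 1e-12)
    }
  }

  # a pair sharing no scored marker is flagged undefined
  sc <- rbind(X = c(1L, 0L, 1L, NA, NA),
              Y = c(NA, NA, NA, 1L, 0L),
              Z = c(1L, 0L, 1L, 1L, 0L))
  colnames(sc) <- panel_columns(tiny_panel())
  dm <- jaccard_matrix(allele_matrix(sc, tiny_panel()))
  expect_true(is.na(dm$d["X", "Y"]))
  expect_identical(dm$n_shared_columns["X", "Y"], 0L)
  expect_false(is.na(dm$d["X", "Z"]))
})

test_that("similarity is 1 - d and preserves symmetry and flags", {
  set.seed(3)
  m <- random_matrix(6)
  dm <- jaccard_matrix(m)
  s <- similarity(dm)
  expect_equal(s, 1 - dm$d)
  expect_equal(s, t(s))
  dm$d[1, 2] <- dm$d[2, 1] <- NA
  expect_true(is.na(similarity(dm)[1, 2]))
})

test_that("nj_tree solves 3 taxa in closed form", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(lens[["a"]], 1)   # (3 + 4 - 5) / 2
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 3)
})

test_that("nj_tree recovers additive trees exactly (topology and lengths)", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- stats::runif(nrow(tr0$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr0)
    tr1 <- nj_tree(D)
    expect_same_topology(ape::unroot(tr0), tr1)
    D1 <- ape::cophenetic.phylo(tr1)[rownames(D), colnames(D)]
    expect_lt(max(abs(D1 - D)), 1e-9)
  }
})

test_that("nj_tree is invariant under input row permutation", {
  set.seed(55)
  M <- matrix(stats::runif(36), 6)
  D <- (M + t(M)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:6), paste0("t", 1:6))
  t1 <- nj_tree(D)
  perm <- sample(1:6)
  t2 <- nj_tree(D[perm, perm])
  expect_same_topology(t1, t2)
  d1 <- ape::cophenetic.phylo(t1)
  d2 <- ape::cophenetic.phylo(t2)[rownames(d1), colnames(d1)]
  expect_lt(max(abs(d1 - d2)), 1e-9)

  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), "undefined|3 samples")
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(nj_tree(Dna), "undefined")
})

test_that("negative NJ branch estimates are clamped and flagged", {
  # classic non-additive configuration forcing a negative estimate
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 9, 9,
                9, 9, 0, 1,
                9, 9, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  # star-like configuration whose central taxon d forces a negative
  # length estimate at the first join
  D2 <- matrix(c(0.000, 0.767, 0.825, 0.263,
                 0.767, 0.000, 0.897, 0.313,
                 0.825, 0.897, 0.000, 0.398,
                 0.263, 0.313, 0.398, 0.000), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr2 <- nj_tree(D2)
  expect_true(all(tr2$edge.length >= 0))
  expect_gte(attr(tr2, "clamped"), 1L)
})

test_that("write_newick round-trips through an independent parser", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("plain", "with space", "pipe|m"),
                              c("plain", "with space", "pipe|m")))
  tr <- nj_tree(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  s <- write_newick(tr, f)
  expect_true(file.exists(f))
  back <- ape::read.tree(f)
  # ape keeps the protective quotes as label characters; strip to compare
  labs <- gsub("^'|'$", "", back$tip.label)
  expect_setequal(labs, tr$tip.label)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)

  set.seed(77)
  m <- random_matrix(7)
  tr2 <- nj_tree(jaccard_matrix(m))
  back2 <- ape::read.tree(text = write_newick(tr2))
  expect_same_topology(tr2, back2)
})

test_that("pcoa reconstructs Euclidean configurations", {
  # 4 collinear points: one positive axis carries everything
  x <- c(0, 1, 3, 7)
  D <- abs(outer(x, x, `-`))
  dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
  o <- ssrkit::pcoa(D, 3)
  expect_equal(o$percent_variation[1], 100, tolerance = 1e-9)
  expect_equal(as.matrix(stats::dist(o$coordinates[, 1, drop = FALSE])), D,
               ignore_attr = TRUE, tolerance = 1e-9)

  set.seed(61)
  X <- matrix(stats::rnorm(60), 12, 5)
  D2 <- as.matrix(stats::dist(X))
  dimnames(D2) <- list(paste0("s", 1:12), paste0("s", 1:12))
  o2 <- ssrkit::pcoa(D2, 11)
  expect_lt(max(abs(as.matrix(stats::dist(o2$coordinates)) - D2)), 1e-9)
  pv <- o2$percent_variation[!is.na(o2$percent_variation)]
  expect_true(all(diff(pv) <= 1e-9))

  # duplicate samples land on the same point
  m <- one_marker_matrix(list(c("1", "2"), c("1", "2"), "3"),
                         as.character(1:4))
  o3 <- ssrkit::pcoa(jaccard_matrix(m), 2)
  expect_equal(o3$coordinates[1, ], o3$coordinates[2, ], tolerance = 1e-9)

  # all-zero distances: degenerate flag, zero coordinates
  Z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  oz <- ssrkit::pcoa(Z, 2)
  expect_true(oz$degenerate)
  expect_true(all(oz$coordinates == 0))
})

test_that("distance and ordination writers emit parseable tables", {
  set.seed(8)
  m <- random_matrix(5)
  dm <- jaccard_matrix(m)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_distances(dm, f1, format = "long")
  long <- utils::read.csv(f1)
  expect_identical(nrow(long), 10L)              # 5 * 4 / 2 pairs
  expect_equal(long$d[long$id1 == "S001" & long$id2 == "S002"],
               dm$d["S001", "S002"], tolerance = 1e-9)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_distances(dm, f2, format = "square")
  sq <- utils::read.csv(f2, check.names = FALSE)
  expect_equal(as.numeric(sq[1, -1]), unname(dm$d[1, ]), tolerance = 1e-9)

  o <- ssrkit::pcoa(dm, 2)
  f3 <- withr::local_tempfile(fileext = ".csv")
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_ordination(o, f3, f4)
  expect_identical(nrow(utils::read.csv(f3)), 5L)
  expect_identical(nrow(utils::read.csv(f4)), 2L)
})
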