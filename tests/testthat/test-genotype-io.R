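test_that("read_matrix round-trips the canonical 0/1/9 dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession_id,MK1_100,MK1_103,MK2_200",
               "A1,1,0,9",
               "A2,1,1,0"), f)
  m <- read_matrix(f)
  expect_s3_class(m, "allele_matrix")
  expect_identical(sample_ids(m), c("A1", "A2"))
  expect_identical(m$panel$markers, c("MK1", "MK2"))
  expect_equal(sum(is.na(m$scores)), 1L)
  expect_identical(unname(m$scores["A2", ]), c(1L, 1L, 0L))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, f2)
  expect_identical(readLines(f2), readLines(f))

  # write then read is the identity for generated matrices too
  set.seed(4)
  m3 <- random_matrix(8, p_missing_block = 0.2)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m3, f3)
  expect_equal(read_matrix(f3)$scores, m3$scores)
})

test_that("panel inference groups columns and recovers size ranges", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession_id,IBS11_224,IBS11_251,IBS11_278,IBS14_188",
               "A1,1,0,1,1"), f)
  m <- read_matrix(f)
  expect_identical(m$panel$markers, c("IBS11", "IBS14"))
  expect_identical(m$panel$alleles$IBS11, c("224", "251", "278"))
  expect_identical(m$panel$size_range$IBS11, c(224L, 278L))
})

test_that("read_matrix rejects malformed files with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession_id,MK1_100,MK1_103", "A1,1,2"), f)
  expect_error(read_matrix(f), "outside \\{0,1,9\\}.*A1.*MK1_103")

  writeLines(c("accession_id,MK1_100", "A1,1", "A1,0"), f)
  expect_error(read_matrix(f), "duplicate")

  writeLines(c("accession_id,MK1_100,MK1_103", "A1,1"), f)
  expect_error(read_matrix(f))          # ragged row

  writeLines(c("accession_id,MK1_100,MK1", "A1,1,0"), f)
  expect_error(read_matrix(f))          # un-parseable column key
})

test_that("write_matrix handles degenerate shapes", {
  panel <- marker_panel("MK1", list(c("100", "103")))
  empty <- allele_matrix(matrix(integer(0), 0L, 2L,
                                dimnames = list(NULL, panel_columns(panel))),
                         panel)
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix(empty, f)
  expect_identical(readLines(f), "accession_id,MK1_100,MK1_103")

  one <- allele_matrix(matrix(c(1L, 0L), 1L, 2L,
                              dimnames = list("A1", panel_columns(panel))),
                       panel)
  write_matrix(one, f)
  expect_identical(readLines(f)[2L], "A1,1,0")
})

test_that("validate_matrix reports block mixing, monomorphism, all-missing", {
  m <- tiny_matrix()
  rep0 <- validate_matrix(m)
  expect_true(rep0$clean)
  expect_identical(nrow(rep0$mixed_blocks), 0L)

  sc <- m$scores
  sc["A1", "MK1_100"] <- NA_integer_            # mixed block
  mixed <- allele_matrix(sc, m$panel)
  rep1 <- validate_matrix(mixed)
  expect_identical(rep1$mixed_blocks$sample_id, "A1")
  expect_identical(rep1$mixed_blocks$marker, "MK1")
  # validate is pure: the matrix is untouched
  expect_identical(mixed$scores, sc)

  sc2 <- m$scores
  sc2[, c("MK2_200", "MK2_204")] <- rep(c(1L, 0L), each = 3L)
  rep2 <- validate_matrix(allele_matrix(sc2, m$panel))
  expect_true("MK2" %in% rep2$monomorphic_markers)

  sc3 <- m$scores
  sc3["A3", ] <- NA_integer_
  rep3 <- validate_matrix(allele_matrix(sc3, m$panel))
  expect_identical(rep3$all_missing_samples, "A3")
})

test_that("block_normalize blanks partially scored blocks only", {
  sc <- tiny_matrix()$scores
  sc["A1", "MK1_100"] <- NA_integer_
  bn <- block_normalize(allele_matrix(sc, tiny_panel()))
  expect_true(all(is.na(bn$scores["A1", 1:3])))
  expect_identical(bn$scores["A1", 4:5], sc["A1", 4:5])
  expect_identical(bn$scores["A2", ], sc["A2", ])
})

test_that("subset_matrix restricts and reorders rows", {
  m <- tiny_matrix()
  expect_equal(subset_matrix(m, sample_ids(m)), m)
  expect_identical(nrow(subset_matrix(m, character(0))$scores), 0L)
  s <- subset_matrix(m, c("A3", "A1"))
  expect_identical(sample_ids(s), c("A3", "A1"))
  expect_error(subset_matrix(m, "nope"), "unknown sample id")

  pp <- passport_table(c("A1", "A2", "A3"),
                       biological_status = c("landrace", "breeding_line",
                                             "landrace"))
  lr <- pp$sample_id[pp$biological_status == "landrace"]
  expect_identical(nrow(subset_matrix(m, lr)$scores), 2L)
})

test_that("merge_matrices unions allele inventories with the fill rule", {
  m <- tiny_matrix()
  panel <- tiny_panel()
  empty <- allele_matrix(matrix(integer(0), 0L, 5L,
                                dimnames = list(NULL, panel_columns(panel))),
                         panel)
  expect_equal(merge_matrices(m, empty)$scores, m$scores)

  # b knows an extra allele 109 at MK1; a scored MK1 -> absent there,
  # a missing MK1 block -> stays missing
  sc_a <- rbind(A1 = c(1L, 0L, 1L, 1L, 0L),
                A2 = c(NA, NA, NA, 0L, 1L))
  colnames(sc_a) <- panel_columns(panel)
  a <- allele_matrix(sc_a, panel)
  panel_b <- marker_panel(c("MK1", "MK2"),
                          alleles = list(c("100", "103", "106", "109"),
                                         c("200", "204")))
  sc_b <- matrix(c(0L, 1L, 0L, 1L, 1L, 0L), 1L,
                 dimnames = list("B1", panel_columns(panel_b)))
  b <- allele_matrix(sc_b, panel_b)
  mg <- merge_matrices(a, b)
  expect_identical(mg$panel$alleles$MK1, c("100", "103", "106", "109"))
  expect_identical(mg$scores["A1", "MK1_109"], 0L)      # scored block
  expect_true(is.na(mg$scores["A2", "MK1_109"]))        # missing block
  expect_identical(nrow(mg$scores), 3L)

  # id collisions get collection-qualified
  two <- merge_matrices(m, m, labels = c("cip", "usda"))
  expect_true(all(c("cip:A1", "usda:A1") %in% sample_ids(two)))

  panel_c <- marker_panel("OTHER", list("1"))
  cmat <- allele_matrix(matrix(1L, 1L, 1L,
                               dimnames = list("C1",
                                               panel_columns(panel_c))),
                        panel_c)
  expect_error(merge_matrices(m, cmat), "incompatible panels")
})

test_that("subset then merge of a row partition reproduces the matrix", {
  set.seed(11)
  m <- random_matrix(10, p_missing_block = 0.15)
  ids <- sample_ids(m)
  left <- subset_matrix(m, ids[1:4])
  right <- subset_matrix(m, ids[5:10])
  back <- merge_matrices(left, right)
  expect_equal(back$scores[ids, ], m$scores)
})

test_that("passport records enforce category and pairing invariants", {
  expect_error(passport_table("A1", biological_status = "weed"),
               "invalid biological_status")
  expect_error(passport_table(c("A1", "A1")),
               "duplicate")
  expect_error(passport_table("A1", sample_source = "mother_plant",
                              paired_with = "A2|invitro"),
               "different accession")
  pp <- passport_table(c("A1", "A1"),
                       sample_source = c("mother_plant", "in_vitro"),
                       paired_with = c("A1|invitro", "A1|mother"))
  expect_identical(pp$sample_id, c("A1|mother", "A1|invitro"))

  f <- withr::local_tempfile(fileext = ".csv")
  write_passport(pp, f)
  expect_equal(read_passport(f)$sample_id, pp$sample_id)
})
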