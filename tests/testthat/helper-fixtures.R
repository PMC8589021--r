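# Hand-built fixtures and independent brute-force oracles shared by the
# test files.  Oracles are deliberately naive (per-pair set arithmetic,
# explicit double sums) and never call the implementation they check.

tiny_panel <- function() {
  marker_panel(c("MK1", "MK2"),
               alleles = list(c("100", "103", "106"), c("200", "204")))
}

# 3 samples x (3 + 2) columns, fully scored
tiny_matrix <- function() {
  sc <- rbind(
    A1 = c(1L, 0L, 1L, 1L, 0L),
    A2 = c(1L, 1L, 0L, 0L, 1L),
    A3 = c(0L, 0L, 1L, 1L, 0L))
  colnames(sc) <- panel_columns(tiny_panel())
  allele_matrix(sc, tiny_panel())
}

random_matrix <- function(n_samples, panel = tiny_panel(), p_present = 0.4,
                          p_missing_block = 0) {
  keys <- panel_columns(panel)
  sc <- matrix(rbinom(n_samples * length(keys), 1L, p_present),
               nrow = n_samples,
               dimnames = list(sprintf("S%03d", seq_len(n_samples)), keys))
  if (p_missing_block > 0) {
    cm <- panel_column_markers(panel)
    for (i in seq_len(n_samples)) {
      for (mk in panel$markers) {
        if (runif(1) < p_missing_block) sc[i, cm == mk] <- NA_integer_
      }
    }
  }
  allele_matrix(sc, panel)
}

# Jaccard for one pair of score rows by explicit set arithmetic over
# co-scored marker blocks; NA when the union of presences is empty.
oracle_jaccard_pair <- function(x, y, col_marker) {
  a <- b <- cc <- 0L
  for (mk in unique(col_marker)) {
    ix <- which(col_marker == mk)
    if (anyNA(x[ix]) || anyNA(y[ix])) next    # block-missing: drop marker
    for (j in ix) {
      if (x[j] == 1L && y[j] == 1L) a <- a + 1L
      else if (x[j] == 1L) b <- b + 1L
      else if (y[j] == 1L) cc <- cc + 1L
    }
  }
  if (a + b + cc == 0L) NA_real_ else 1 - a / (a + b + cc)
}

# Botstein PIC by literal evaluation of the published double sum.
oracle_pic <- function(p) {
  p <- p[p > 0]
  n <- length(p)
  dsum <- 0
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) dsum <- dsum + 2 * p[i]^2 * p[j]^2
    }
  }
  1 - sum(p^2) - dsum
}

expect_same_topology <- function(t1, t2) {
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
}

# matrix whose rows present the given allele-label sets at a one-marker
# panel (labels drawn from `alleles`)
one_marker_matrix <- function(sets, alleles) {
  panel <- marker_panel("MK", list(alleles))
  sc <- t(vapply(sets, function(s) as.integer(alleles %in% s),
                 integer(length(alleles))))
  rownames(sc) <- sprintf("S%02d", seq_along(sets))
  colnames(sc) <- panel_columns(panel)
  allele_matrix(sc, panel)
}
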