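#' Unweighted neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration with the Studier-Keppler Q-criterion
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j}.  At each step the pair with
#' minimal Q is joined; ties are broken deterministically by the lowest
#' (row, column) index pair in the current matrix order (input order, new
#' clusters appended last).  Negative branch-length estimates are clamped
#' to zero and flagged via the `"clamped"` attribute.  On an additive
#' (tree-metric) input the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param dm a `dist_matrix` from [jaccard_matrix()], or any symmetric
#'   numeric matrix with dimnames.  No undefined (`NA`) distances allowed.
#' @return an unrooted `phylo` object (class from the \pkg{ape} package);
#'   attribute `"clamped"` counts clamped branches.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist_matrix")) {
    D <- dm$d
  } else {
    D <- as.matrix(dm)
  }
  if (anyNA(D)) {
    stop("distance matrix has undefined entries; impute or drop those ",
         "samples before tree building")
  }
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 samples")
  ids <- rownames(D) %||% paste0("t", seq_len(n))

  # active[k] = node id of cluster in row k of D; tips are 1..n, internal
  # nodes are numbered by creation step and renumbered at the end so the
  # final join is n+1 (ape convention).
  active <- seq_len(n)
  next_internal <- n + 1L
  edge <- matrix(0L, 0L, 2L)
  elen <- numeric(0)
  clamped <- 0L

  clamp <- function(x) max(x, 0)

  while (length(active) > 3L) {
    na <- length(active)
    r <- rowSums(D)
    Q <- (na - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (na - 2))
    lj <- D[i, j] - li
    if (li < 0 || lj < 0) clamped <- clamped + sum(c(li, lj) < 0)
    li <- clamp(li); lj <- clamp(lj)

    u <- next_internal; next_internal <- next_internal + 1L
    edge <- rbind(edge, c(u, active[i]), c(u, active[j]))
    elen <- c(elen, li, lj)

    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(na), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], u)
  }

  # final three-point join (closed form)
  x <- 1L; y <- 2L; z <- 3L
  lx <- (D[x, y] + D[x, z] - D[y, z]) / 2
  ly <- (D[x, y] + D[y, z] - D[x, z]) / 2
  lz <- (D[x, z] + D[y, z] - D[x, y]) / 2
  if (any(c(lx, ly, lz) < 0)) clamped <- clamped + sum(c(lx, ly, lz) < 0)
  u <- next_internal
  edge <- rbind(edge, c(u, active[x]), c(u, active[y]), c(u, active[z]))
  elen <- c(elen, clamp(lx), clamp(ly), clamp(lz))

  # renumber internal nodes so the root (last created) is n+1 and parents
  # precede children, as ape expects
  n_internal <- u - n
  remap <- c(seq_len(n), (2L * n - 1L) - seq_len(n_internal))
  edge <- matrix(remap[edge], ncol = 2L)

  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = ids, Nnode = n_internal),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "clamped") <- clamped
  tr
}

#' Write a tree in Newick format
#'
#' Serializes a `phylo` tree with branch lengths.  Labels containing
#' characters outside `[A-Za-z0-9_.+-]` are single-quoted (internal quotes
#' doubled), so ids with spaces or `|` source qualifiers survive a
#' round-trip through standard Newick parsers.
#'
#' @param t a `phylo` object (e.g. from [nj_tree()]).
#' @param path file path; when `NULL` the Newick string is returned.
#' @return invisibly the Newick string (always returned invisibly; visible
#'   when `path` is `NULL`).
#' @export
write_newick <- function(t, path = NULL) {
  stopifnot(inherits(t, "phylo"))
  n <- length(t$tip.label)
  kids <- split(seq_len(nrow(t$edge)), t$edge[, 1L])
  quote_label <- function(x) {
    if (grepl("[^A-Za-z0-9_.+-]", x)) {
      paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
    } else x
  }
  fmt_len <- function(l) {
    if (is.null(t$edge.length)) "" else paste0(":", sprintf("%.10g", l))
  }
  rec <- function(node, elen) {
    if (node <= n) {
      paste0(quote_label(t$tip.label[node]), fmt_len(elen))
    } else {
      rows <- kids[[as.character(node)]]
      inner <- vapply(rows, function(r) rec(t$edge[r, 2L],
                                            t$edge.length[r]),
                      character(1))
      paste0("(", paste(inner, collapse = ","), ")",
             if (!is.na(elen)) fmt_len(elen) else "")
    }
  }
  root <- setdiff(t$edge[, 1L], t$edge[, 2L])[1L]
  s <- paste0(rec(root, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  invisible(s)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of \eqn{-\tfrac12 d^2}, eigendecomposition, and
#' coordinates scaled by the square root of the eigenvalues.  Jaccard
#' distances are generally non-Euclidean, so some eigenvalues may be
#' negative; those axes are dropped and their magnitude reported
#' separately, and percent variation is taken over positive eigenvalues
#' only.
#'
#' @param dm a `dist_matrix` or symmetric numeric matrix (no `NA`).
#' @param n_axes number of leading axes to retain (capped at the number of
#'   positive eigenvalues).
#' @return list of class `ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `percent_variation` (per retained
#'   axis), `negative_eigenvalue_mass`, `degenerate` (TRUE when all
#'   distances are zero).
#' @export
pcoa <- function(dm, n_axes = 2L) {
  D <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (anyNA(D)) stop("undefined distances; impute or drop samples first")
  if (n_axes < 1L) stop("n_axes must be >= 1")
  n <- nrow(D)
  ids <- rownames(D) %||% paste0("s", seq_len(n))
  if (all(D == 0)) {
    co <- matrix(0, n, n_axes, dimnames = list(ids, paste0("Axis", 1:n_axes)))
    return(structure(list(coordinates = co, eigenvalues = rep(0, n),
                          percent_variation = rep(NA_real_, n_axes),
                          negative_eigenvalue_mass = 0, degenerate = TRUE),
                     class = "ordination"))
  }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  ev <- eig$values
  pos <- ev > max(ev) * 1e-12
  k <- min(n_axes, sum(pos))
  co <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  if (k < n_axes) {
    co <- cbind(co, matrix(0, n, n_axes - k))
  }
  dimnames(co) <- list(ids, paste0("Axis", seq_len(n_axes)))
  pct <- rep(NA_real_, n_axes)
  pct[seq_len(k)] <- ev[seq_len(k)] / sum(ev[pos]) * 100
  structure(list(coordinates = co, eigenvalues = ev,
                 percent_variation = pct,
                 negative_eigenvalue_mass = sum(abs(ev[ev < 0])),
                 degenerate = FALSE),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " axes; % variation: ",
      paste(format(x$percent_variation, digits = 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write ordination results
#' @param ord an `ordination` from [pcoa()].
#' @param coords_path CSV path for sample coordinates.
#' @param eigen_path optional CSV path for eigenvalue / percent table.
#' @return invisibly, `coords_path`.
#' @export
write_ordination <- function(ord, coords_path, eigen_path = NULL) {
  df <- data.frame(id = rownames(ord$coordinates), ord$coordinates,
                   check.names = FALSE)
  utils::write.csv(df, coords_path, row.names = FALSE, quote = FALSE)
  if (!is.null(eigen_path)) {
    k <- ncol(ord$coordinates)
    utils::write.csv(
      data.frame(axis = seq_len(k),
                 eigenvalue = ord$eigenvalues[seq_len(k)],
                 percent_variation = ord$percent_variation),
      eigen_path, row.names = FALSE, quote = FALSE)
  }
  invisible(coords_path)
}
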