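# Layered global-alignment DAG with affine gap costs.
#
# Every coordinate pair (i, j), 0 <= i <= n, 0 <= j <= m, carries three
# nodes: C(i,j) (match state), D(i,j) (inside a gap consuming A) and I(i,j)
# (inside a gap consuming B).  Edges and weights:
#
#   C(i,j) -> C(i+1,j+1)  M[A[i+1], B[j+1]]   (match/mismatch)
#   C(i,j) -> D(i+1,j)    p + g               (gap open, consumes A[i+1])
#   C(i,j) -> I(i,j+1)    p + g               (gap open, consumes B[j+1])
#   D(i,j) -> D(i+1,j)    g                   (gap extend)
#   I(i,j) -> I(i,j+1)    g                   (gap extend)
#   D(i,j) -> C(i,j)      0                   (gap close)
#   I(i,j) -> C(i,j)      0                   (gap close)
#
# so a length-l gap accumulates exactly p + l*g.  s = C(0,0), t = C(n,m);
# s-t paths are in bijection with global alignments of A and B.  The graph
# is kept implicit: the topology is fixed, so score tables, edge masks and
# counts are stored as (n+1) x (m+1) matrices per layer, indexed [i+1, j+1].

#' Build the alignment DAG of two sequences
#'
#' @param seq_a,seq_b residue strings (may be empty). `seq_a` is the
#'   representative/reference sequence A of length n, `seq_b` the member
#'   sequence B of length m.
#' @param scoring a [scoring_scheme()].
#' @param gap_model `"affine"` (default; gap of length l scores p + l*g via
#'   the three-layer construction) or `"linear"` (gap scores l*g; every gap
#'   residue is an open-close step, so s-t paths are in bijection with the
#'   monotone lattice paths counted by the Delannoy numbers).
#' @return object of class `alignment_graph` (implicit C/D/I layered DAG).
#' @examples
#' g <- build_alignment_graph("ARN", "ARN", scoring_scheme())
#' compute_score_tables(g)$opt
#' @export
build_alignment_graph <- function(seq_a, seq_b, scoring = scoring_scheme(),
                                  gap_model = c("affine", "linear")) {
  gap_model <- match.arg(gap_model)
  stopifnot(inherits(scoring, "scoring_scheme"))
  a <- .encode_sequence(seq_a, scoring, "seq_a")
  b <- .encode_sequence(seq_b, scoring, "seq_b")
  M <- .score_matrix_for(scoring, a, b)
  n <- length(a); m <- length(b)
  # per-diagonal-edge substitution score, sub[i, j] = M[A[i], B[j]] (1-based)
  sub <- if (n > 0L && m > 0L) {
    matrix(M[cbind(rep(match(a, rownames(M)), m),
                   rep(match(b, colnames(M)), each = n))], n, m)
  } else {
    matrix(numeric(0), n, m)
  }
  structure(list(seq_a = seq_a, seq_b = seq_b, a = a, b = b, n = n, m = m,
                 sub = sub, scoring = scoring, gap_model = gap_model),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat("<alignment_graph> ", x$n, " x ", x$m,
      " residues (", 3L * (x$n + 1L) * (x$m + 1L), " layered nodes)\n",
      sep = "")
  invisible(x)
}

#' Prefix and suffix optimal-score tables
#'
#' Computes, for every node v of the alignment DAG, the best s-to-v path
#' weight (prefix, `r*`) and the best v-to-t path weight (suffix, `w*`), by
#' one dynamic-programming sweep per direction in (reverse) topological
#' order.  Unreachable states carry `-Inf`.  `opt` is the optimal global
#' alignment score.
#'
#' @param graph an [build_alignment_graph()] result.
#' @return object of class `score_tables`: matrices `rc, rd, ri` (prefix)
#'   and `wc, wd, wi` (suffix), each (n+1) x (m+1), plus `opt`.
#' @export
compute_score_tables <- function(graph) {
  stopifnot(inherits(graph, "alignment_graph"))
  n <- graph$n; m <- graph$m
  affine <- graph$gap_model == "affine"
  p <- if (affine) graph$scoring$gap_open else 0
  g <- graph$scoring$gap_extend
  sub <- graph$sub
  ninf <- -Inf
  dims <- c(n + 1L, m + 1L)

  # suffix: best weight from node to t = C(n,m)
  wc <- matrix(ninf, dims[1], dims[2])
  wd <- matrix(ninf, dims[1], dims[2])
  wi <- matrix(ninf, dims[1], dims[2])
  for (i in n:0) {
    for (j in m:0) {
      ii <- i + 1L; jj <- j + 1L
      if (i == n && j == m) {
        wc[ii, jj] <- 0
      } else {
        best <- ninf
        if (i < n && j < m) best <- max(best, sub[i + 1L, j + 1L] + wc[ii + 1L, jj + 1L])
        if (i < n) best <- max(best, p + g + wd[ii + 1L, jj])
        if (j < m) best <- max(best, p + g + wi[ii, jj + 1L])
        wc[ii, jj] <- best
      }
      wd[ii, jj] <- max(wc[ii, jj],
                        if (affine && i < n) g + wd[ii + 1L, jj] else ninf)
      wi[ii, jj] <- max(wc[ii, jj],
                        if (affine && j < m) g + wi[ii, jj + 1L] else ninf)
    }
  }

  # prefix: best weight from s = C(0,0) to node
  rc <- matrix(ninf, dims[1], dims[2])
  rd <- matrix(ninf, dims[1], dims[2])
  ri <- matrix(ninf, dims[1], dims[2])
  for (i in 0:n) {
    for (j in 0:m) {
      ii <- i + 1L; jj <- j + 1L
      rd[ii, jj] <- if (i > 0)
        max(p + g + rc[ii - 1L, jj],
            if (affine) g + rd[ii - 1L, jj] else ninf) else ninf
      ri[ii, jj] <- if (j > 0)
        max(p + g + rc[ii, jj - 1L],
            if (affine) g + ri[ii, jj - 1L] else ninf) else ninf
      if (i == 0 && j == 0) {
        rc[ii, jj] <- 0
      } else {
        best <- max(rd[ii, jj], ri[ii, jj])
        if (i > 0 && j > 0) best <- max(best, sub[i, j] + rc[ii - 1L, jj - 1L])
        rc[ii, jj] <- best
      }
    }
  }

  structure(list(rc = rc, rd = rd, ri = ri, wc = wc, wd = wd, wi = wi,
                 opt = rc[n + 1L, m + 1L], n = n, m = m),
            class = "score_tables")
}

#' Extract the Delta-suboptimal subgraph
#'
#' An edge e = (u, v) belongs to the subgraph iff
#' `prefix(u) + w(e) + suffix(v) >= OPT - delta`, i.e. iff some s-t path of
#' weight at least OPT - delta crosses it.  The subgraph contains every
#' Delta-suboptimal alignment path (and possibly some worse s-t paths — the
#' standard minimal-subgraph approximation).  Nodes not on any qualifying
#' path have no incident kept edges.
#'
#' @param graph an [build_alignment_graph()] result.
#' @param tables matching [compute_score_tables()] result.
#' @param delta nonnegative integer score slack; `Inf` keeps every edge on
#'   any s-t path (the full alignment DAG).
#' @return object of class `suboptimal_subgraph`: seven logical edge masks
#'   (`keep_m`, `keep_od`, `keep_oi`, `keep_ed`, `keep_ei`, `keep_cd`,
#'   `keep_ci`) plus the parent graph, tables and `delta`.
#' @export
extract_delta_subgraph <- function(graph, tables, delta) {
  stopifnot(inherits(graph, "alignment_graph"),
            inherits(tables, "score_tables"))
  if (length(delta) != 1L || is.na(delta) || delta < 0 ||
      (is.finite(delta) && delta != floor(delta))) {
    stop("`delta` must be a single nonnegative integer (or Inf)")
  }
  n <- graph$n; m <- graph$m
  affine <- graph$gap_model == "affine"
  p <- if (affine) graph$scoring$gap_open else 0
  g <- graph$scoring$gap_extend
  thr <- tables$opt - delta
  ge <- function(x) !is.na(x) & x >= thr
  ia <- seq_len(n); ja <- seq_len(m)          # 1-based residue indices
  i0 <- seq_len(n + 1L); j0 <- seq_len(m + 1L)

  with(tables, {
    # match: C(i,j) -> C(i+1,j+1), tails i in 0..n-1, j in 0..m-1
    keep_m <- if (n > 0 && m > 0)
      ge(rc[ia, ja, drop = FALSE] + graph$sub + wc[ia + 1L, ja + 1L, drop = FALSE])
      else matrix(logical(0), n, m)
    # gap opens
    keep_od <- if (n > 0)
      ge(rc[ia, j0, drop = FALSE] + p + g + wd[ia + 1L, j0, drop = FALSE])
      else matrix(logical(0), n, m + 1L)
    keep_oi <- if (m > 0)
      ge(rc[i0, ja, drop = FALSE] + p + g + wi[i0, ja + 1L, drop = FALSE])
      else matrix(logical(0), n + 1L, m)
    # gap extends (absent under the linear gap model)
    keep_ed <- if (n > 0 && affine)
      ge(rd[ia, j0, drop = FALSE] + g + wd[ia + 1L, j0, drop = FALSE])
      else matrix(FALSE, n, m + 1L)
    keep_ei <- if (m > 0 && affine)
      ge(ri[i0, ja, drop = FALSE] + g + wi[i0, ja + 1L, drop = FALSE])
      else matrix(FALSE, n + 1L, m)
    # gap closes (same coordinate)
    keep_cd <- ge(rd + wc)
    keep_ci <- ge(ri + wc)
    structure(list(graph = graph, tables = tables, delta = delta,
                   keep_m = keep_m, keep_od = keep_od, keep_oi = keep_oi,
                   keep_ed = keep_ed, keep_ei = keep_ei,
                   keep_cd = keep_cd, keep_ci = keep_ci),
              class = "suboptimal_subgraph")
  })
}

#' @export
print.suboptimal_subgraph <- function(x, ...) {
  ne <- sum(x$keep_m) + sum(x$keep_od) + sum(x$keep_oi) + sum(x$keep_ed) +
    sum(x$keep_ei) + sum(x$keep_cd) + sum(x$keep_ci)
  cat("<suboptimal_subgraph> delta = ", x$delta, ", ", ne, " edges kept\n",
      sep = "")
  invisible(x)
}

#' Edges of a suboptimal subgraph as a tibble
#'
#' One row per kept edge with tail/head layer and coordinates and the edge
#' weight. Mostly used by tests and small-instance inspection.
#'
#' @param subgraph an [extract_delta_subgraph()] result.
#' @return tibble with columns `type`, `ui`, `uj`, `ulayer`, `vi`, `vj`,
#'   `vlayer`, `weight`.
#' @export
subgraph_edges <- function(subgraph) {
  stopifnot(inherits(subgraph, "suboptimal_subgraph"))
  g <- subgraph$graph
  p <- g$scoring$gap_open; gx <- g$scoring$gap_extend
  rows <- list()
  grab <- function(mask, type, ulayer, vlayer, di, dj, weight) {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    ui <- idx[, 1] - 1L; uj <- idx[, 2] - 1L
    w <- if (type == "match") g$sub[idx] else weight
    tibble::tibble(type = type, ui = ui, uj = uj, ulayer = ulayer,
                   vi = ui + di, vj = uj + dj, vlayer = vlayer, weight = w)
  }
  out <- list(
    grab(subgraph$keep_m, "match", "C", "C", 1L, 1L, NA_real_),
    grab(subgraph$keep_od, "open_d", "C", "D", 1L, 0L, p + gx),
    grab(subgraph$keep_oi, "open_i", "C", "I", 0L, 1L, p + gx),
    grab(subgraph$keep_ed, "extend_d", "D", "D", 1L, 0L, gx),
    grab(subgraph$keep_ei, "extend_i", "I", "I", 0L, 1L, gx),
    grab(subgraph$keep_cd, "close_d", "D", "C", 0L, 0L, 0),
    grab(subgraph$keep_ci, "close_i", "I", "C", 0L, 0L, 0))
  dplyr::bind_rows(out)
}
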