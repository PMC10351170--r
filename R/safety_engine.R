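# (alpha, Delta)-safety windows: locate the spanning path P* that carries
# every alpha-safe subpath (alpha > 0.5), then sweep it with a two-pointer
# scan emitting maximal alpha-safe intervals.  All threshold comparisons are
# exact: p >= num/den is tested as den * d_r(v_L) * d(v_R) >= num * d(s) in
# big-integer arithmetic.  The double shadow counts serve only to skip
# comparisons that are far from the boundary (margin 0.05).

.PREFILTER_MARGIN <- 0.05

# exact test  dr * d / total >= num/den,  with double prefilter
.prop_ge <- function(dr, d, total, num, den, sdr = NA, sd = NA, stotal = NA) {
  approx <- sdr * sd / stotal
  if (is.finite(approx)) {
    if (approx >= num / den + .PREFILTER_MARGIN) return(TRUE)
    if (approx <= num / den - .PREFILTER_MARGIN) return(FALSE)
  }
  bi_cmp(bi_mul(bi(den), bi_mul(dr, d)), bi_mul(bi(num), total)) >= 0L
}

.check_alpha <- function(alpha) {
  a <- .alpha_rational(alpha)
  if (2 * a$num <= a$den || a$num > a$den) {
    stop("`alpha` must lie in (0.5, 1]: below 0.5 the alpha-safe paths ",
         "need not lie on a single spanning alignment path")
  }
  a
}

# topological key of a node: anti-diagonal first, gap layers before C
.topo_key <- function(layer, i, j) 2 * (i + j) + as.integer(layer == "C")

.same_node <- function(a, b) {
  a$layer == b$layer && a$i == b$i && a$j == b$j
}

#' Alpha-safe edges of a suboptimal subgraph
#'
#' Returns the kept edges whose exact crossing proportion (Eq. 2) is at
#' least `alpha`.
#'
#' @param subgraph an [extract_delta_subgraph()] result.
#' @param counts matching [count_paths()] result.
#' @param alpha threshold in (0, 1]; exact decimal or `"num/den"` string.
#' @return tibble of edges (`type, ui, uj, vi, vj, ulayer, vlayer`).
#' @export
safe_edges <- function(subgraph, counts, alpha) {
  a <- .alpha_rational(alpha)
  num <- a$num; den <- a$den
  stotal <- counts$total_dbl
  out <- list()
  for (type in c("match", "open_d", "open_i", "extend_d", "extend_i",
                 "close_d", "close_i")) {
    mask <- switch(type, match = subgraph$keep_m, open_d = subgraph$keep_od,
                   open_i = subgraph$keep_oi, extend_d = subgraph$keep_ed,
                   extend_i = subgraph$keep_ei, close_d = subgraph$keep_cd,
                   close_i = subgraph$keep_ci)
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) next
    tl <- .edge_tail_layer(type)
    keeprow <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      ui <- idx[r, 1] - 1L; uj <- idx[r, 2] - 1L
      h <- .edge_head(type, ui, uj)
      keeprow[r] <- .prop_ge(.node_dr(counts, tl, ui, uj),
                             .node_d(counts, h$layer, h$i, h$j),
                             counts$total, num, den,
                             .node_sdr(counts, tl, ui, uj),
                             .node_sd(counts, h$layer, h$i, h$j), stotal)
    }
    if (any(keeprow)) {
      ui <- unname(idx[keeprow, 1] - 1L); uj <- unname(idx[keeprow, 2] - 1L)
      hh <- lapply(seq_along(ui), function(r) .edge_head(type, ui[r], uj[r]))
      out[[type]] <- tibble::tibble(
        type = type, ui = ui, uj = uj, ulayer = tl,
        vi = vapply(hh, `[[`, integer(1) + 0L, "i"),
        vj = vapply(hh, `[[`, integer(1) + 0L, "j"),
        vlayer = vapply(hh, `[[`, character(1), "layer"))
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(type = character(), ui = integer(), uj = integer(),
                          ulayer = character(), vi = integer(),
                          vj = integer(), vlayer = character())
  }
  dplyr::arrange(res, .topo_key(ulayer, ui, uj))
}

# alpha-safe nodes (p(v) = dr(v) d(v) / total >= alpha), as tibble layer,i,j
.safe_nodes <- function(counts, num, den) {
  stotal <- counts$total_dbl
  out <- list()
  for (layer in c("C", "D", "I")) {
    dr <- switch(layer, C = counts$srC, D = counts$srD, I = counts$srI)
    d <- switch(layer, C = counts$sC, D = counts$sD, I = counts$sI)
    cand <- which(dr > 0 & d > 0, arr.ind = TRUE)
    if (!nrow(cand)) next
    keeprow <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1] - 1L; j <- cand[r, 2] - 1L
      keeprow[r] <- .prop_ge(.node_dr(counts, layer, i, j),
                             .node_d(counts, layer, i, j),
                             counts$total, num, den,
                             dr[cand[r, 1], cand[r, 2]],
                             d[cand[r, 1], cand[r, 2]], stotal)
    }
    if (any(keeprow)) {
      out[[layer]] <- tibble::tibble(layer = layer,
                                     i = unname(cand[keeprow, 1] - 1L),
                                     j = unname(cand[keeprow, 2] - 1L))
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) res <- tibble::tibble(layer = character(), i = integer(),
                                        j = integer())
  dplyr::arrange(res, .topo_key(layer, i, j))
}

# deterministic edge preference at a node (tie-break rule): at C try match,
# then the gap consuming A, then the gap consuming B; inside a gap close
# before extending
.pref_edges <- function(layer) {
  switch(layer, C = c("match", "open_d", "open_i"),
         D = c("close_d", "extend_d"), I = c("close_i", "extend_i"))
}

# deterministic path between two nodes of the kept subgraph, inclusive of
# both endpoints; backward reachability over the bounding rectangle, then a
# greedy forward walk using the preference order
.connect <- function(subgraph, from, to) {
  if (.same_node(from, to)) {
    return(tibble::tibble(layer = from$layer, i = from$i, j = from$j))
  }
  i0 <- from$i; j0 <- from$j; i1 <- to$i; j1 <- to$j
  stopifnot(i0 <= i1, j0 <= j1)
  nr <- i1 - i0 + 1L; nc <- j1 - j0 + 1L
  reach <- list(C = matrix(FALSE, nr, nc), D = matrix(FALSE, nr, nc),
                I = matrix(FALSE, nr, nc))
  reach[[to$layer]][i1 - i0 + 1L, j1 - j0 + 1L] <- TRUE
  at <- function(lay, i, j) {
    i >= i0 && i <= i1 && j >= j0 && j <= j1 &&
      reach[[lay]][i - i0 + 1L, j - j0 + 1L]
  }
  for (i in i1:i0) {
    for (j in j1:j0) {
      for (lay in c("C", "D", "I")) {
        if (at(lay, i, j)) next      # target cell already TRUE
        ok <- FALSE
        for (type in .pref_edges(lay)) {
          if (!.edge_kept(subgraph, type, i, j)) next
          h <- .edge_head(type, i, j)
          if (at(h$layer, h$i, h$j)) { ok <- TRUE; break }
        }
        if (ok) reach[[lay]][i - i0 + 1L, j - j0 + 1L] <- TRUE
      }
    }
  }
  cur <- from
  path <- list(cur)
  guard <- 4L * (nr + nc + 2L)
  while (!.same_node(cur, to)) {
    advanced <- FALSE
    for (type in .pref_edges(cur$layer)) {
      if (!.edge_kept(subgraph, type, cur$i, cur$j)) next
      h <- .edge_head(type, cur$i, cur$j)
      if (at(h$layer, h$i, h$j)) {
        cur <- h
        path[[length(path) + 1L]] <- cur
        advanced <- TRUE
        break
      }
    }
    if (!advanced) stop("internal error: no path between spanning-path anchors")
    guard <- guard - 1L
    if (guard < 0L) stop("internal error: path search did not terminate")
  }
  tibble::tibble(layer = vapply(path, `[[`, character(1), "layer"),
                 i = vapply(path, `[[`, 0L + integer(1), "i"),
                 j = vapply(path, `[[`, 0L + integer(1), "j"))
}

#' Find the spanning alignment path P*
#'
#' For `alpha > 0.5` there is a single s-t path containing every alpha-safe
#' subpath (any two items crossed by more than half of all paths must share
#' a path).  The path is built by sorting the alpha-safe edges and nodes in
#' topological order and stitching consecutive anchors with a deterministic
#' depth-limited search restricted to the rectangle between them; ties are
#' broken by the fixed edge-preference order (match, gap-in-B-consuming-A,
#' gap-consuming-B; close before extend), making the result reproducible.
#'
#' @param subgraph an [extract_delta_subgraph()] result.
#' @param counts matching [count_paths()] result.
#' @param alpha threshold in (0.5, 1].
#' @return tibble of P* nodes in order: `layer`, `i`, `j`.
#' @export
find_spanning_path <- function(subgraph, counts, alpha) {
  a <- .check_alpha(alpha)
  nodes <- .safe_nodes(counts, a$num, a$den)
  edges <- safe_edges(subgraph, counts, alpha)
  # anchor list sorted topologically; an edge sorts at its tail's key and
  # after the tail node's own anchor
  anchors <- dplyr::bind_rows(
    dplyr::mutate(nodes, kind = "node", key = .topo_key(layer, i, j)),
    if (nrow(edges)) tibble::tibble(kind = "edge", type = edges$type,
                                    layer = edges$ulayer, i = edges$ui,
                                    j = edges$uj,
                                    key = .topo_key(edges$ulayer, edges$ui,
                                                    edges$uj))
    else NULL)
  anchors <- anchors[order(anchors$key,
                           match(anchors$kind, c("node", "edge"))), ]
  n <- subgraph$graph$n; m <- subgraph$graph$m
  cur <- list(layer = "C", i = 0L, j = 0L)
  path <- tibble::tibble(layer = "C", i = 0L, j = 0L)
  append_path <- function(path, seg) {
    if (nrow(seg) > 1L) rbind(path, seg[-1L, c("layer", "i", "j")]) else path
  }
  for (r in seq_len(nrow(anchors))) {
    an <- anchors[r, ]
    if (an$kind == "node") {
      nd <- list(layer = an$layer, i = as.integer(an$i), j = as.integer(an$j))
      if (.same_node(cur, nd)) next
      seg <- .connect(subgraph, cur, nd)
      path <- append_path(path, seg)
      cur <- nd
    } else {
      tail_nd <- list(layer = an$layer, i = as.integer(an$i),
                      j = as.integer(an$j))
      if (!.same_node(cur, tail_nd)) {
        seg <- .connect(subgraph, cur, tail_nd)
        path <- append_path(path, seg)
        cur <- tail_nd
      }
      h <- .edge_head(an$type, an$i, an$j)
      cur <- list(layer = h$layer, i = h$i, j = h$j)
      path <- rbind(path, tibble::tibble(layer = cur$layer, i = cur$i,
                                         j = cur$j))
    }
  }
  tnode <- list(layer = "C", i = n, j = m)
  if (!.same_node(cur, tnode)) {
    seg <- .connect(subgraph, cur, tnode)
    path <- append_path(path, seg)
  }
  path
}

#' Compute maximal (alpha, Delta)-safety windows
#'
#' Two-pointer sweep over the spanning path P*: the right pointer R visits
#' every node; the left pointer L is advanced minimally until the interval
#' [L, R] is alpha-safe (its Eq.-3 proportion is at least alpha), and the
#' interval is emitted when it is also right-maximal.  Windows are reported
#' left to right with exact proportions; subpaths whose projections are
#' empty on both sequences (pure gap-state transitions) are discarded.
#'
#' @param subgraph an [extract_delta_subgraph()] result.
#' @param alpha threshold in (0.5, 1].
#' @param merge if `TRUE`, join windows that intersect or are adjacent on
#'   the representative (A) projection; merged proportions are recomputed
#'   over the spanned subpath and flagged.
#' @param counts optional precomputed [count_paths()] table.
#' @return tibble with one row per window: P* node span (`L`, `R`),
#'   endpoints `i1, j1, i2, j2`, projections `a_start, a_end, b_start,
#'   b_end` (0-based, between-characters), `proportion`,
#'   `proportion_exact`, `merged`.
#' @export
compute_safety_windows <- function(subgraph, alpha, merge = FALSE,
                                   counts = NULL) {
  a <- .check_alpha(alpha)
  if (is.null(counts)) counts <- count_paths(subgraph)
  pstar <- find_spanning_path(subgraph, counts, alpha)
  K <- nrow(pstar)
  drL <- lapply(seq_len(K), function(r)
    .node_dr(counts, pstar$layer[r], pstar$i[r], pstar$j[r]))
  dR <- lapply(seq_len(K), function(r)
    .node_d(counts, pstar$layer[r], pstar$i[r], pstar$j[r]))
  sdrL <- vapply(seq_len(K), function(r)
    .node_sdr(counts, pstar$layer[r], pstar$i[r], pstar$j[r]), 0)
  sdR <- vapply(seq_len(K), function(r)
    .node_sd(counts, pstar$layer[r], pstar$i[r], pstar$j[r]), 0)
  safe <- function(L, R) {
    .prop_ge(drL[[L]], dR[[R]], counts$total, a$num, a$den,
             sdrL[L], sdR[R], counts$total_dbl)
  }
  wins <- list()
  L <- 1L
  for (R in seq_len(K)) {
    while (L <= R && !safe(L, R)) L <- L + 1L
    if (L > R) next
    if (R == K || !safe(L, R + 1L)) {
      wins[[length(wins) + 1L]] <- c(L = L, R = R)
    }
  }
  rows <- list()
  for (w in wins) {
    L <- w[["L"]]; R <- w[["R"]]
    i1 <- pstar$i[L]; j1 <- pstar$j[L]; i2 <- pstar$i[R]; j2 <- pstar$j[R]
    if (i1 == i2 && j1 == j2) next   # empty projection on both sequences
    pr <- exact_ratio(bi_mul(drL[[L]], dR[[R]]), counts$total)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      L = L, R = R, i1 = i1, j1 = j1, i2 = i2, j2 = j2,
      a_start = i1, a_end = i2, b_start = j1, b_end = j2,
      proportion = as.numeric(pr),
      proportion_exact = format(pr, digits = 9L),
      merged = FALSE)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else .empty_windows()
  out <- dplyr::mutate(out, window = dplyr::row_number(), .before = 1L)
  if (merge && nrow(out) > 1L) out <- merge_windows(out, counts, pstar)
  attr(out, "pstar") <- pstar
  attr(out, "alpha") <- a
  out
}

.empty_windows <- function() {
  tibble::tibble(L = integer(), R = integer(), i1 = integer(),
                 j1 = integer(), i2 = integer(), j2 = integer(),
                 a_start = integer(), a_end = integer(),
                 b_start = integer(), b_end = integer(),
                 proportion = numeric(), proportion_exact = character(),
                 merged = logical())
}

#' Merge intersecting or adjacent safety windows
#'
#' Joins windows whose projections on the representative sequence (A)
#' intersect or are adjacent, spanning the union.  The proportion of a
#' merged window is recomputed exactly over the spanned subpath of P* and
#' may fall below alpha; merged rows are flagged.
#'
#' @param windows a [compute_safety_windows()] tibble (sorted along P*).
#' @param counts the matching [count_paths()] table.
#' @param pstar the matching spanning path (attribute `pstar` of the
#'   windows tibble, supplied explicitly).
#' @return tibble in the same layout.
#' @export
merge_windows <- function(windows, counts, pstar = attr(windows, "pstar")) {
  if (is.null(pstar)) stop("`pstar` is required to recompute proportions")
  if (nrow(windows) <= 1L) return(windows)
  groups <- integer(nrow(windows))
  gid <- 1L
  groups[1] <- gid
  for (r in 2L:nrow(windows)) {
    if (windows$a_start[r] <= windows$a_end[r - 1L]) {
      groups[r] <- gid
    } else {
      gid <- gid + 1L
      groups[r] <- gid
    }
  }
  rows <- lapply(split(seq_len(nrow(windows)), groups), function(idx) {
    if (length(idx) == 1L) return(windows[idx, ])
    L <- windows$L[idx[1]]; R <- windows$R[idx[length(idx)]]
    pr <- path_proportion(counts, pstar[L:R, ])
    tibble::tibble(
      window = NA_integer_, L = L, R = R,
      i1 = pstar$i[L], j1 = pstar$j[L], i2 = pstar$i[R], j2 = pstar$j[R],
      a_start = pstar$i[L], a_end = pstar$i[R],
      b_start = pstar$j[L], b_end = pstar$j[R],
      proportion = as.numeric(pr),
      proportion_exact = format(pr, digits = 9L),
      merged = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, window = dplyr::row_number())
}
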