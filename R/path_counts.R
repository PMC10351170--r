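# Exact s-t path counting on the suboptimal subgraph (Eq.-1-style
# recurrences in both directions).  Counts are exact big integers; a
# double-precision shadow of every table is kept purely as a conservative
# prefilter so that exact big-integer comparisons are only done near the
# decision boundary.

#' Count s-t paths through every node of a suboptimal subgraph
#'
#' For every node v, `d(v)` is the exact number of v-to-t paths and
#' `d_r(v)` the exact number of s-to-v paths, both restricted to kept
#' edges.  `total = d(s) = d_r(t)` is the number of s-t paths of the
#' subgraph.  All counts are exact (arbitrary-precision integers).
#'
#' @param subgraph an [extract_delta_subgraph()] result.
#' @return object of class `path_count_table` holding per-layer list
#'   matrices of big integers (`dC,dD,dI,drC,drD,drI`), matching double
#'   shadows (`sC,...,srI`), the exact `total` and the parent subgraph.
#' @export
count_paths <- function(subgraph) {
  stopifnot(inherits(subgraph, "suboptimal_subgraph"))
  n <- subgraph$graph$n; m <- subgraph$graph$m
  km <- subgraph$keep_m; kod <- subgraph$keep_od; koi <- subgraph$keep_oi
  ked <- subgraph$keep_ed; kei <- subgraph$keep_ei
  kcd <- subgraph$keep_cd; kci <- subgraph$keep_ci
  Z <- structure(numeric(0), class = "bigint")
  ONE <- bi(1)
  newL <- function() matrix(list(Z), n + 1L, m + 1L)
  newS <- function() matrix(0, n + 1L, m + 1L)

  dC <- newL(); dD <- newL(); dI <- newL()
  sC <- newS(); sD <- newS(); sI <- newS()
  for (i in n:0) {
    for (j in m:0) {
      ii <- i + 1L; jj <- j + 1L
      # C layer
      acc <- Z; sacc <- 0
      if (i == n && j == m) { acc <- ONE; sacc <- 1 }
      if (i < n && j < m && km[ii, jj]) {
        acc <- bi_add(acc, dC[[ii + 1L, jj + 1L]]); sacc <- sacc + sC[ii + 1L, jj + 1L]
      }
      if (i < n && kod[ii, jj]) {
        acc <- bi_add(acc, dD[[ii + 1L, jj]]); sacc <- sacc + sD[ii + 1L, jj]
      }
      if (j < m && koi[ii, jj]) {
        acc <- bi_add(acc, dI[[ii, jj + 1L]]); sacc <- sacc + sI[ii, jj + 1L]
      }
      dC[[ii, jj]] <- acc; sC[ii, jj] <- sacc
      # D layer
      acc <- Z; sacc <- 0
      if (kcd[ii, jj]) { acc <- dC[[ii, jj]]; sacc <- sC[ii, jj] }
      if (i < n && ked[ii, jj]) {
        acc <- bi_add(acc, dD[[ii + 1L, jj]]); sacc <- sacc + sD[ii + 1L, jj]
      }
      dD[[ii, jj]] <- acc; sD[ii, jj] <- sacc
      # I layer
      acc <- Z; sacc <- 0
      if (kci[ii, jj]) { acc <- dC[[ii, jj]]; sacc <- sC[ii, jj] }
      if (j < m && kei[ii, jj]) {
        acc <- bi_add(acc, dI[[ii, jj + 1L]]); sacc <- sacc + sI[ii, jj + 1L]
      }
      dI[[ii, jj]] <- acc; sI[ii, jj] <- sacc
    }
  }

  drC <- newL(); drD <- newL(); drI <- newL()
  srC <- newS(); srD <- newS(); srI <- newS()
  for (i in 0:n) {
    for (j in 0:m) {
      ii <- i + 1L; jj <- j + 1L
      # D layer (in-edges: open from C(i-1,j), extend from D(i-1,j))
      acc <- Z; sacc <- 0
      if (i > 0 && kod[ii - 1L, jj]) {
        acc <- bi_add(acc, drC[[ii - 1L, jj]]); sacc <- sacc + srC[ii - 1L, jj]
      }
      if (i > 0 && ked[ii - 1L, jj]) {
        acc <- bi_add(acc, drD[[ii - 1L, jj]]); sacc <- sacc + srD[ii - 1L, jj]
      }
      drD[[ii, jj]] <- acc; srD[ii, jj] <- sacc
      # I layer
      acc <- Z; sacc <- 0
      if (j > 0 && koi[ii, jj - 1L]) {
        acc <- bi_add(acc, drC[[ii, jj - 1L]]); sacc <- sacc + srC[ii, jj - 1L]
      }
      if (j > 0 && kei[ii, jj - 1L]) {
        acc <- bi_add(acc, drI[[ii, jj - 1L]]); sacc <- sacc + srI[ii, jj - 1L]
      }
      drI[[ii, jj]] <- acc; srI[ii, jj] <- sacc
      # C layer (in-edges: match from C(i-1,j-1), closes from D/I(i,j))
      acc <- Z; sacc <- 0
      if (i == 0 && j == 0) { acc <- ONE; sacc <- 1 }
      if (i > 0 && j > 0 && km[ii - 1L, jj - 1L]) {
        acc <- bi_add(acc, drC[[ii - 1L, jj - 1L]]); sacc <- sacc + srC[ii - 1L, jj - 1L]
      }
      if (kcd[ii, jj]) { acc <- bi_add(acc, drD[[ii, jj]]); sacc <- sacc + srD[ii, jj] }
      if (kci[ii, jj]) { acc <- bi_add(acc, drI[[ii, jj]]); sacc <- sacc + srI[ii, jj] }
      drC[[ii, jj]] <- acc; srC[ii, jj] <- sacc
    }
  }

  total <- dC[[1L, 1L]]
  if (bi_is_zero(total)) stop("subgraph has no s-t path")
  structure(list(dC = dC, dD = dD, dI = dI, drC = drC, drD = drD, drI = drI,
                 sC = sC, sD = sD, sI = sI, srC = srC, srD = srD, srI = srI,
                 total = total, total_dbl = sC[1L, 1L],
                 subgraph = subgraph, n = n, m = m),
            class = "path_count_table")
}

#' @export
print.path_count_table <- function(x, ...) {
  cat("<path_count_table> ", x$n, " x ", x$m, "; total s-t paths = ",
      bi_to_char(x$total), "\n", sep = "")
  invisible(x)
}

# node accessors; node = list/df-row with layer ("C","D","I"), i, j
.node_d <- function(counts, layer, i, j) {
  switch(layer, C = counts$dC, D = counts$dD, I = counts$dI)[[i + 1L, j + 1L]]
}
.node_dr <- function(counts, layer, i, j) {
  switch(layer, C = counts$drC, D = counts$drD, I = counts$drI)[[i + 1L, j + 1L]]
}
.node_sd <- function(counts, layer, i, j) {
  switch(layer, C = counts$sC, D = counts$sD, I = counts$sI)[i + 1L, j + 1L]
}
.node_sdr <- function(counts, layer, i, j) {
  switch(layer, C = counts$srC, D = counts$srD, I = counts$srI)[i + 1L, j + 1L]
}

# head node of an edge given its type and tail coordinates
.edge_head <- function(type, ui, uj) {
  switch(type,
         match    = list(layer = "C", i = ui + 1L, j = uj + 1L),
         open_d   = list(layer = "D", i = ui + 1L, j = uj),
         open_i   = list(layer = "I", i = ui, j = uj + 1L),
         extend_d = list(layer = "D", i = ui + 1L, j = uj),
         extend_i = list(layer = "I", i = ui, j = uj + 1L),
         close_d  = list(layer = "C", i = ui, j = uj),
         close_i  = list(layer = "C", i = ui, j = uj),
         stop("unknown edge type: ", type))
}

.edge_tail_layer <- function(type) {
  switch(type, match = "C", open_d = "C", open_i = "C",
         extend_d = "D", extend_i = "I", close_d = "D", close_i = "I")
}

.edge_kept <- function(subgraph, type, ui, uj) {
  mask <- switch(type, match = subgraph$keep_m, open_d = subgraph$keep_od,
                 open_i = subgraph$keep_oi, extend_d = subgraph$keep_ed,
                 extend_i = subgraph$keep_ei, close_d = subgraph$keep_cd,
                 close_i = subgraph$keep_ci)
  ii <- ui + 1L; jj <- uj + 1L
  ii <= nrow(mask) && jj <= ncol(mask) && isTRUE(mask[ii, jj])
}

#' Proportion of s-t paths crossing an edge
#'
#' Eq.-2 quantity `p(e) = d_r(u) d(v) / d(s)`, exact.
#'
#' @param counts a [count_paths()] result.
#' @param edge a list or one-row data frame with `type` (one of `match`,
#'   `open_d`, `open_i`, `extend_d`, `extend_i`, `close_d`, `close_i`) and
#'   tail coordinates `ui`, `uj`.
#' @return an `exact_ratio` (use `as.numeric()` / `format()`).
#' @export
edge_proportion <- function(counts, edge) {
  stopifnot(inherits(counts, "path_count_table"))
  type <- edge$type; ui <- edge$ui; uj <- edge$uj
  if (!.edge_kept(counts$subgraph, type, ui, uj)) {
    stop("edge ", type, "(", ui, ",", uj, ") is not in the subgraph")
  }
  h <- .edge_head(type, ui, uj)
  num <- bi_mul(.node_dr(counts, .edge_tail_layer(type), ui, uj),
                .node_d(counts, h$layer, h$i, h$j))
  exact_ratio(num, counts$total)
}

#' Proportion of s-t paths containing a contiguous subpath
#'
#' Eq.-3 quantity `p(P) = d_r(v1) d(vk) / d(s)`, exact.  The path must be a
#' contiguous subpath of the subgraph (consecutive nodes joined by kept
#' edges); this is verified.
#'
#' @param counts a [count_paths()] result.
#' @param path data frame with columns `layer`, `i`, `j`, one row per node
#'   in order.
#' @return an `exact_ratio`.
#' @export
path_proportion <- function(counts, path) {
  stopifnot(inherits(counts, "path_count_table"), nrow(path) >= 1L)
  k <- nrow(path)
  if (k > 1L) {
    for (r in seq_len(k - 1L)) {
      type <- .edge_between(path$layer[r], path$i[r], path$j[r],
                            path$layer[r + 1L], path$i[r + 1L], path$j[r + 1L])
      if (is.null(type) ||
          !.edge_kept(counts$subgraph, type, path$i[r], path$j[r])) {
        stop("nodes ", r, " and ", r + 1L,
             " are not joined by a kept edge; not a contiguous subpath")
      }
    }
  }
  num <- bi_mul(.node_dr(counts, path$layer[1], path$i[1], path$j[1]),
                .node_d(counts, path$layer[k], path$i[k], path$j[k]))
  exact_ratio(num, counts$total)
}

# identify the edge type joining two adjacent nodes, or NULL
.edge_between <- function(l1, i1, j1, l2, i2, j2) {
  di <- i2 - i1; dj <- j2 - j1
  if (l1 == "C" && l2 == "C" && di == 1 && dj == 1) return("match")
  if (l1 == "C" && l2 == "D" && di == 1 && dj == 0) return("open_d")
  if (l1 == "C" && l2 == "I" && di == 0 && dj == 1) return("open_i")
  if (l1 == "D" && l2 == "D" && di == 1 && dj == 0) return("extend_d")
  if (l1 == "I" && l2 == "I" && di == 0 && dj == 1) return("extend_i")
  if (l1 == "D" && l2 == "C" && di == 0 && dj == 0) return("close_d")
  if (l1 == "I" && l2 == "C" && di == 0 && dj == 0) return("close_i")
  NULL
}
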