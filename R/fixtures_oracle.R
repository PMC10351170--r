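# Brute-force oracles and seeded synthetic clusters.  The oracles
# re-derive every quantity by exhaustive enumeration, independently of the
# DAG/counting machinery, and are the ground truth for the engine's
# property tests.  Hard small-instance guards: enumeration is exponential.

.ORACLE_GUARD <- 14L

#' Delannoy numbers
#'
#' `D(n, m)` counts monotone lattice paths from (0,0) to (n,m) with unit
#' and diagonal steps — exactly the number of global alignments of
#' sequences of lengths n and m.  Independent three-term recurrence
#' `D(i,j) = D(i-1,j) + D(i,j-1) + D(i-1,j-1)`.
#'
#' @param n,m nonnegative integers.
#' @return exact count (double; exact up to 2^53).
#' @examples
#' delannoy(2, 2)  # 13
#' delannoy(3, 3)  # 63
#' @export
delannoy <- function(n, m) {
  stopifnot(n >= 0, m >= 0)
  D <- matrix(1, n + 1L, m + 1L)
  if (n > 0 && m > 0) {
    for (i in 2:(n + 1L)) {
      for (j in 2:(m + 1L)) {
        D[i, j] <- D[i - 1L, j] + D[i, j - 1L] + D[i - 1L, j - 1L]
      }
    }
  }
  D[n + 1L, m + 1L]
}

# enumerate every global alignment of a and b as op strings over
# M (match column), D (A residue vs gap), I (gap vs B residue)
.enumerate_ops <- function(n, m) {
  if (n + m > .ORACLE_GUARD) {
    stop("sequences too long for exhaustive enumeration (n + m <= ",
         .ORACLE_GUARD, ")")
  }
  rec <- function(i, j) {
    if (i == n && j == m) return("")
    out <- character(0)
    if (i < n && j < m) out <- c(out, paste0("M", rec_memo(i + 1L, j + 1L)))
    if (i < n) out <- c(out, paste0("D", rec_memo(i + 1L, j)))
    if (j < m) out <- c(out, paste0("I", rec_memo(i, j + 1L)))
    out
  }
  memo <- new.env(parent = emptyenv())
  rec_memo <- function(i, j) {
    key <- paste0(i, ",", j)
    if (is.null(memo[[key]])) memo[[key]] <- rec(i, j)
    memo[[key]]
  }
  rec_memo(0L, 0L)
}

# affine score of an op string, computed directly from the gap formula
.score_ops <- function(ops, a_chars, b_chars, M, p, g) {
  if (!nchar(ops)) return(0)
  op <- strsplit(ops, "", fixed = TRUE)[[1]]
  i <- 0L; j <- 0L
  score <- 0
  prev <- ""
  for (o in op) {
    if (o == "M") {
      i <- i + 1L; j <- j + 1L
      score <- score + M[a_chars[i], b_chars[j]]
    } else if (o == "D") {
      i <- i + 1L
      score <- score + g + if (prev == "D") 0 else p
    } else {
      j <- j + 1L
      score <- score + g + if (prev == "I") 0 else p
    }
    prev <- o
  }
  score
}

# node sequence (layered C/D/I path) of an op string, as "L:i:j" keys
.ops_to_nodes <- function(ops) {
  nodes <- "C:0:0"
  i <- 0L; j <- 0L
  prev <- ""
  op <- if (nchar(ops)) strsplit(ops, "", fixed = TRUE)[[1]] else character(0)
  for (o in op) {
    if (prev %in% c("D", "I") && o != prev) {
      nodes <- c(nodes, paste0("C:", i, ":", j))   # close the gap
    }
    if (o == "M") {
      i <- i + 1L; j <- j + 1L
      nodes <- c(nodes, paste0("C:", i, ":", j))
    } else if (o == "D") {
      i <- i + 1L
      nodes <- c(nodes, paste0("D:", i, ":", j))
    } else {
      j <- j + 1L
      nodes <- c(nodes, paste0("I:", i, ":", j))
    }
    prev <- o
  }
  if (prev %in% c("D", "I")) nodes <- c(nodes, paste0("C:", i, ":", j))
  nodes
}

#' Enumerate all Delta-suboptimal global alignments
#'
#' Exhaustive recursion over every alignment (no graph machinery), exact
#' affine scores via the gap formula p + l*g, filtered to score >=
#' OPT - delta.  Guarded to n + m <= 14.
#'
#' @inheritParams align_safety
#' @param delta nonnegative suboptimality slack; `Inf` returns every
#'   alignment.
#' @return tibble `ops`, `a_aln`, `b_aln`, `score`, sorted by decreasing
#'   score; attribute `opt` holds the optimal score.
#' @export
enumerate_alignments <- function(seq_a, seq_b, scoring = scoring_scheme(),
                                 delta = 0) {
  stopifnot(delta >= 0)
  a_chars <- .encode_sequence(seq_a, scoring, "seq_a")
  b_chars <- .encode_sequence(seq_b, scoring, "seq_b")
  M <- .score_matrix_for(scoring, a_chars, b_chars)
  p <- scoring$gap_open; g <- scoring$gap_extend
  ops <- .enumerate_ops(length(a_chars), length(b_chars))
  scores <- vapply(ops, .score_ops, 0, a_chars, b_chars, M, p, g,
                   USE.NAMES = FALSE)
  opt <- if (length(scores)) max(scores) else 0
  keep <- scores >= opt - delta
  ops <- ops[keep]; scores <- scores[keep]
  ord <- order(-scores, ops)
  ops <- ops[ord]; scores <- scores[ord]
  gapped <- function(o, chars, consume) {
    oo <- if (nchar(o)) strsplit(o, "", fixed = TRUE)[[1]] else character(0)
    k <- 0L
    paste(vapply(oo, function(x) {
      if (x %in% consume) { k <<- k + 1L; chars[k] } else "-"
    }, ""), collapse = "")
  }
  out <- tibble::tibble(
    ops = ops,
    a_aln = vapply(ops, gapped, "", a_chars, c("M", "D"), USE.NAMES = FALSE),
    b_aln = vapply(ops, gapped, "", b_chars, c("M", "I"), USE.NAMES = FALSE),
    score = scores)
  attr(out, "opt") <- opt
  out
}

# all compositions of L into ordered positive parts (2^(L-1)), filtered to
# at most max_parts parts
.compositions <- function(L, max_parts) {
  if (max_parts < 1L) return(list())
  if (L == 0L) return(list(integer(0)))
  out <- list()
  for (first in seq_len(L)) {
    rest <- if (first == L) list(integer(0))
            else .compositions(L - first, max_parts - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(first, r)
  }
  out
}

# every layered-graph s-t path representing the alignment `ops`, allowing
# gap runs to be split into several open/close parts, with at most
# max_extra extra opens in total; returns list of list(nodes, extra)
.ops_to_layer_paths <- function(ops, max_extra) {
  op <- if (nchar(ops)) strsplit(ops, "", fixed = TRUE)[[1]] else character(0)
  # run-length encode
  runs <- if (length(op)) rle(op) else list(values = character(0),
                                            lengths = integer(0))
  states <- list(list(nodes = "C:0:0", extra = 0L, i = 0L, j = 0L))
  for (k in seq_along(runs$values)) {
    v <- runs$values[k]; L <- runs$lengths[k]
    nxt <- list()
    for (st in states) {
      if (v == "M") {
        nodes <- st$nodes; i <- st$i; j <- st$j
        for (q in seq_len(L)) {
          i <- i + 1L; j <- j + 1L
          nodes <- c(nodes, paste0("C:", i, ":", j))
        }
        nxt[[length(nxt) + 1L]] <- list(nodes = nodes, extra = st$extra,
                                        i = i, j = j)
      } else {
        lay <- if (v == "D") "D" else "I"
        for (comp in .compositions(L, max_extra - st$extra + 1L)) {
          nodes <- st$nodes; i <- st$i; j <- st$j
          for (part in comp) {
            for (q in seq_len(part)) {
              if (lay == "D") i <- i + 1L else j <- j + 1L
              nodes <- c(nodes, paste0(lay, ":", i, ":", j))
            }
            nodes <- c(nodes, paste0("C:", i, ":", j))
          }
          nxt[[length(nxt) + 1L]] <- list(nodes = nodes,
                                          extra = st$extra +
                                            length(comp) - 1L,
                                          i = i, j = j)
        }
      }
    }
    states <- nxt
  }
  states
}

# every Delta-suboptimal s-t path of the layered graph, by enumerating all
# alignments and all gap-split structures within the score budget
.enumerate_layer_paths <- function(seq_a, seq_b, scoring, delta) {
  all_aln <- enumerate_alignments(seq_a, seq_b, scoring, delta = Inf)
  opt <- attr(all_aln, "opt")
  p <- scoring$gap_open
  paths <- list()
  for (r in seq_len(nrow(all_aln))) {
    slack <- all_aln$score[r] - (opt - delta)
    if (slack < 0) next
    max_extra <- if (p < 0) as.integer(slack %/% (-p)) else .Machine$integer.max
    for (st in .ops_to_layer_paths(all_aln$ops[r], max_extra)) {
      paths[[length(paths) + 1L]] <- list(nodes = st$nodes,
                                          weight = all_aln$score[r] +
                                            st$extra * p)
    }
  }
  attr(paths, "opt") <- opt
  paths
}

# all s-t paths of the graph given by an explicit edge set (keys "u>v"),
# enumerated by depth-first search with deterministic neighbor order
.paths_of_edge_set <- function(edge_keys, s_key, t_key, cap = 2e5) {
  splits <- strsplit(edge_keys, ">", fixed = TRUE)
  adj <- split(vapply(splits, `[`, "", 2L), vapply(splits, `[`, "", 1L))
  adj <- lapply(adj, function(v) sort(unique(v)))
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 64L)
  acc$np <- 0L
  walk <- function(node, trail) {
    trail <- c(trail, node)
    if (node == t_key) {
      acc$np <- acc$np + 1L
      if (acc$np > cap) stop("path enumeration exceeded cap of ", cap)
      if (acc$np > length(acc$paths)) {
        acc$paths <- c(acc$paths, vector("list", length(acc$paths)))
      }
      acc$paths[[acc$np]] <- trail
      return(invisible())
    }
    for (nb in adj[[node]]) walk(nb, trail)
  }
  walk(s_key, character(0))
  acc$paths[seq_len(acc$np)]
}

#' Exhaustive-enumeration oracle for safety windows
#'
#' Enumerates the relevant s-t path set of the layered alignment graph
#' explicitly — every alignment and every gap-split structure within the
#' score budget — and computes every contiguous subpath's exact containment
#' proportion by counting, keeping the maximal alpha-safe subpaths.  Mode
#' `"subgraph"` uses all s-t paths of the minimal subgraph induced by the
#' Delta-suboptimal paths (the engine's definition, which may include some
#' non-suboptimal paths); mode `"suboptimal"` restricts to the true
#' Delta-suboptimal paths, quantifying that approximation.
#'
#' @inheritParams align_safety
#' @param mode `"subgraph"` (engine-equivalent) or `"suboptimal"`.
#' @return windows tibble (`i1, j1, i2, j2`, projections, `proportion`,
#'   exact integer ratio `prop_num`/`prop_den`) sorted along the
#'   alignment; attribute `n_paths` holds the path-set size.
#' @export
oracle_safety_windows <- function(seq_a, seq_b, scoring = scoring_scheme(),
                                  alpha = 0.75, delta = 0,
                                  mode = c("subgraph", "suboptimal")) {
  mode <- match.arg(mode)
  a <- .check_alpha(alpha)
  sub <- .enumerate_layer_paths(seq_a, seq_b, scoring, delta)
  if (mode == "suboptimal") {
    paths <- lapply(sub, `[[`, "nodes")
  } else {
    edge_keys <- unique(unlist(lapply(sub, function(pp) {
      nd <- pp$nodes
      if (length(nd) < 2L) character(0)
      else paste(nd[-length(nd)], nd[-1L], sep = ">")
    })))
    if (is.null(edge_keys) || !length(edge_keys)) {
      paths <- list("C:0:0")
    } else {
      n <- nchar(seq_a); m <- nchar(seq_b)
      paths <- .paths_of_edge_set(edge_keys, "C:0:0",
                                  paste0("C:", n, ":", m))
    }
  }
  S <- length(paths)
  path_strs <- vapply(paths, function(nd)
    paste0(";", paste(nd, collapse = ";"), ";"), "")
  # any alpha-safe subpath (alpha > 0.5) occurs in more than half the
  # paths, hence in at least one of any majority subset: enumerate
  # candidate subpaths from such a subset
  src <- if (S <= 400L) seq_len(S) else seq_len(S %/% 2L + 1L)
  cands <- unique(unlist(lapply(paths[src], function(nd) {
    k <- length(nd)
    unlist(lapply(seq_len(k), function(l)
      vapply(l:k, function(r) paste(nd[l:r], collapse = ";"), "")))
  })))
  counts <- vapply(cands, function(q)
    sum(grepl(paste0(";", q, ";"), path_strs, fixed = TRUE)), 0L,
    USE.NAMES = FALSE)
  safe <- counts * a$den >= a$num * S
  cands <- cands[safe]; counts <- counts[safe]
  if (length(cands)) {
    maximal <- vapply(seq_along(cands), function(k) {
      !any(vapply(seq_along(cands), function(l)
        l != k && grepl(cands[k], cands[l], fixed = TRUE), logical(1)))
    }, logical(1))
    cands <- cands[maximal]; counts <- counts[maximal]
  }
  rows <- list()
  for (k in seq_along(cands)) {
    nd <- strsplit(cands[k], ";", fixed = TRUE)[[1]]
    first <- strsplit(nd[1], ":", fixed = TRUE)[[1]]
    last <- strsplit(nd[length(nd)], ":", fixed = TRUE)[[1]]
    i1 <- as.integer(first[2]); j1 <- as.integer(first[3])
    i2 <- as.integer(last[2]); j2 <- as.integer(last[3])
    if (i1 == i2 && j1 == j2) next   # empty projection on both sequences
    rows[[length(rows) + 1L]] <- tibble::tibble(
      i1 = i1, j1 = j1, i2 = i2, j2 = j2,
      a_start = i1, a_end = i2, b_start = j1, b_end = j2,
      proportion = counts[k] / S, prop_num = counts[k], prop_den = S)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(i1 = integer(), j1 = integer(), i2 = integer(),
                   j2 = integer(), a_start = integer(), a_end = integer(),
                   b_start = integer(), b_end = integer(),
                   proportion = numeric(), prop_num = integer(),
                   prop_den = integer())
  out <- dplyr::arrange(out, i1 + j1, i1, i2 + j2)
  attr(out, "n_paths") <- S
  attr(out, "opt") <- attr(sub, "opt")
  out
}

# ---- synthetic clusters ---------------------------------------------------

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")

#' Generate a seeded synthetic protein cluster
#'
#' The representative is drawn uniformly over the 20 standard residues;
#' members are copies with independent per-residue substitutions and
#' uniform-length indels.  A ground-truth mask marks representative
#' residues never substituted or deleted in any member — usable as a
#' stand-in stable label for metric tests (it is a conservation mask, not
#' a real structure annotation).  Identical seeds give identical clusters;
#' the caller's RNG state is preserved.
#'
#' @param n_members number of member sequences. Default 4.
#' @param length representative length in residues. Default 120.
#' @param sub_rate per-residue substitution probability. Default 0.15.
#' @param indel_rate per-position indel probability. Default 0.03.
#' @param max_indel_len maximum indel length (uniform 1..max). Default 5.
#' @param seed integer random seed.
#' @param id_prefix sequence ID prefix.
#' @return list with `cluster` (a `seq_cluster`) and `conserved` (logical
#'   mask over representative positions).
#' @export
generate_cluster <- function(n_members = 4, length = 120, sub_rate = 0.15,
                             indel_rate = 0.03, max_indel_len = 5,
                             seed = 1, id_prefix = "syn") {
  stopifnot(n_members >= 1, length >= 1,
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            max_indel_len >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  rep_chars <- sample(.AA20, length, replace = TRUE)
  touched <- logical(length)
  members <- character(n_members)
  for (k in seq_len(n_members)) {
    chars <- rep_chars
    subs <- stats::runif(length) < sub_rate
    if (any(subs)) {
      chars[subs] <- vapply(chars[subs], function(cc)
        sample(setdiff(.AA20, cc), 1L), "")
      touched <- touched | subs
    }
    # indels anchored at representative positions, applied right-to-left so
    # earlier anchor coordinates stay valid
    pieces <- as.list(chars)
    ind <- which(stats::runif(length) < indel_rate)
    for (pos in rev(ind)) {
      len <- sample.int(max_indel_len, 1L)
      if (stats::runif(1) < 0.5) {           # deletion of rep positions
        del <- pos:min(length, pos + len - 1L)
        pieces[del] <- list("")
        touched[del] <- TRUE
      } else {                               # insertion after pos
        ins <- paste(sample(.AA20, len, replace = TRUE), collapse = "")
        pieces[[pos]] <- paste0(pieces[[pos]], ins)
      }
    }
    members[k] <- paste(unlist(pieces), collapse = "")
  }
  ids <- paste0(id_prefix, "_", c("rep", sprintf("m%02d", seq_len(n_members))))
  cluster <- structure(
    list(representative = stats::setNames(paste(rep_chars, collapse = ""),
                                          ids[1]),
         members = stats::setNames(members, ids[-1]),
         source = NA_character_),
    class = "seq_cluster")
  list(cluster = cluster, conserved = !touched)
}

#' Annotation table from a conservation mask
#'
#' Synthetic stand-in annotation: conserved positions become a stable type
#' and all others an unstable type, in the schema of
#' [read_structure_annotation()].
#'
#' @param mask logical vector over sequence positions.
#' @param id sequence ID.
#' @param stable_type,unstable_type structure type names.
#' @return annotation tibble.
#' @export
annotation_from_mask <- function(mask, id, stable_type = "AlphaHelix",
                                 unstable_type = "Coil") {
  tibble::tibble(id = id, pos = seq_along(mask) - 1L,
                 type = ifelse(mask, stable_type, unstable_type),
                 stable = !(ifelse(mask, stable_type, unstable_type) %in%
                              .UNSTABLE_TYPES))
}
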