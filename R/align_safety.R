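#' Alignment-safety analysis of one sequence pair
#'
#' Builds the affine-gap alignment DAG of the representative `seq_a` and
#' member `seq_b`, extracts the Delta-suboptimal subgraph, counts its s-t
#' paths exactly, and computes the maximal (alpha, Delta)-safety windows —
#' the intervals common to at least a proportion `alpha` of all s-t paths
#' of the subgraph (which include every Delta-suboptimal alignment).
#'
#' @param seq_a representative residue string (length n).
#' @param seq_b member residue string (length m).
#' @param scoring a [scoring_scheme()]; BLOSUM62 with gap open -11 /
#'   extend -1 by default.
#' @param alpha safety proportion threshold in (0.5, 1]. Default 0.75.
#' @param delta nonnegative integer suboptimality slack (same scale as the
#'   substitution scores). Default 8.
#' @param merge join intersecting/adjacent windows (the window-merge mode);
#'   merged proportions are recomputed and flagged. Default `FALSE`.
#' @return object of class `safety_alignment`; see [tidy.safety_alignment()]
#'   and [glance.safety_alignment()].
#' @examples
#' fit <- align_safety("HEAGAWGHEE", "PAWHEAE", alpha = 0.75, delta = 8)
#' tidy(fit)
#' glance(fit)
#' @export
align_safety <- function(seq_a, seq_b, scoring = scoring_scheme(),
                         alpha = 0.75, delta = 8, merge = FALSE) {
  a <- .check_alpha(alpha)
  graph <- build_alignment_graph(seq_a, seq_b, scoring)
  tables <- compute_score_tables(graph)
  subgraph <- extract_delta_subgraph(graph, tables, delta)
  counts <- count_paths(subgraph)
  windows <- compute_safety_windows(subgraph, alpha, merge = merge,
                                    counts = counts)
  structure(
    list(windows = windows, pstar = attr(windows, "pstar"),
         opt = tables$opt, n_paths = bi_to_char(counts$total),
         n_paths_dbl = counts$total_dbl,
         alpha = as.numeric(a$num) / as.numeric(a$den),
         alpha_rational = a, delta = delta, merge = merge,
         n = graph$n, m = graph$m, seq_a = seq_a, seq_b = seq_b,
         scoring = scoring),
    class = "safety_alignment")
}

#' Safety windows of a sequence pair as a tibble
#'
#' Convenience wrapper around [align_safety()] returning the windows tibble
#' directly.
#'
#' @inheritParams align_safety
#' @return tibble of maximal safety windows (see
#'   [compute_safety_windows()]).
#' @export
safety_windows <- function(seq_a, seq_b, scoring = scoring_scheme(),
                           alpha = 0.75, delta = 8, merge = FALSE) {
  tidy(align_safety(seq_a, seq_b, scoring, alpha, delta, merge))
}

#' @export
print.safety_alignment <- function(x, ...) {
  cat("<safety_alignment> ", x$n, " x ", x$m, " residues; alpha = ",
      x$alpha, ", delta = ", x$delta, "\n", sep = "")
  cat("  optimal score ", x$opt, "; ", x$n_paths,
      " s-t paths in the suboptimal subgraph\n", sep = "")
  cat("  ", nrow(x$windows), " safety windows\n", sep = "")
  invisible(x)
}

#' @rdname align_safety
#' @param x a `safety_alignment`.
#' @param ... unused.
#' @export
tidy.safety_alignment <- function(x, ...) {
  out <- x$windows
  attr(out, "pstar") <- NULL
  attr(out, "alpha") <- NULL
  out
}

#' One-row summary of a safety-alignment fit
#'
#' @param x a `safety_alignment`.
#' @param ... unused.
#' @return tibble with optimal score, exact path count (as character, the
#'   count routinely exceeds double precision), window count and the safety
#'   coverage of both sequences.
#' @export
glance.safety_alignment <- function(x, ...) {
  w <- x$windows
  cov_a <- if (x$n > 0) sum(.interval_mask(w$a_start, w$a_end, x$n)) / x$n
           else NA_real_
  cov_b <- if (x$m > 0) sum(.interval_mask(w$b_start, w$b_end, x$m)) / x$m
           else NA_real_
  tibble::tibble(n = x$n, m = x$m, alpha = x$alpha, delta = x$delta,
                 opt_score = x$opt, n_paths = x$n_paths,
                 n_windows = nrow(w),
                 mean_window_length = if (nrow(w)) mean(w$a_end - w$a_start)
                                      else NA_real_,
                 coverage_a = cov_a, coverage_b = cov_b)
}

# logical residue mask covered by 0-based half-open intervals
.interval_mask <- function(starts, ends, len) {
  mask <- logical(len)
  for (k in seq_along(starts)) {
    if (ends[k] > starts[k]) mask[(starts[k] + 1L):ends[k]] <- TRUE
  }
  mask
}

#' Deterministic optimal global alignment
#'
#' Traceback of one optimal alignment through the optimal-path subgraph
#' (Delta = 0), using the package-wide deterministic tie-break (match, then
#' gap consuming A, then gap consuming B; close before extend).
#'
#' @inheritParams align_safety
#' @return list with `a_aln`, `b_aln` (gapped strings), `score`, `columns`
#'   and `identity` (identical aligned pairs / alignment columns; `NA` for
#'   empty alignments).
#' @export
optimal_alignment <- function(seq_a, seq_b, scoring = scoring_scheme()) {
  graph <- build_alignment_graph(seq_a, seq_b, scoring)
  tables <- compute_score_tables(graph)
  g0 <- extract_delta_subgraph(graph, tables, 0)
  cur <- list(layer = "C", i = 0L, j = 0L)
  a_chars <- graph$a; b_chars <- graph$b
  acol <- character(0); bcol <- character(0)
  while (!(cur$layer == "C" && cur$i == graph$n && cur$j == graph$m)) {
    step <- NULL
    for (type in .pref_edges(cur$layer)) {
      if (.edge_kept(g0, type, cur$i, cur$j)) { step <- type; break }
    }
    if (is.null(step)) stop("internal error: optimal traceback stuck")
    h <- .edge_head(step, cur$i, cur$j)
    if (step == "match") {
      acol <- c(acol, a_chars[cur$i + 1L]); bcol <- c(bcol, b_chars[cur$j + 1L])
    } else if (step %in% c("open_d", "extend_d")) {
      acol <- c(acol, a_chars[cur$i + 1L]); bcol <- c(bcol, "-")
    } else if (step %in% c("open_i", "extend_i")) {
      acol <- c(acol, "-"); bcol <- c(bcol, b_chars[cur$j + 1L])
    }
    cur <- h
  }
  columns <- length(acol)
  ident <- if (columns == 0L) NA_real_
           else sum(acol == bcol & acol != "-") / columns
  list(a_aln = paste(acol, collapse = ""), b_aln = paste(bcol, collapse = ""),
       score = tables$opt, columns = columns, identity = ident)
}

#' Fraction of identical aligned residue pairs
#'
#' @param alignment an [optimal_alignment()] result (or any list with
#'   `a_aln` and `b_aln` gapped strings).
#' @return identical pairs / alignment columns; `NA` for empty alignments.
#' @export
pairwise_identity <- function(alignment) {
  a <- strsplit(alignment$a_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$b_aln, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(NA_real_)
  sum(a == b & a != "-") / length(a)
}
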