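# Structure-retention benchmarking: relate safety-window projections to
# stable/unstable per-residue secondary-structure labels.
#
# A residue is a true positive (TP) when it is both safe and stable, a
# false negative (FN) when stable but not safe, and a false positive (FP)
# when safe but not stable.  Retention (recall) = TP/(TP+FN), overlap
# (precision) = TP/(TP+FP), F1 = their harmonic mean.

#' Per-residue confusion counts for one sequence
#'
#' Residues without an annotation record are excluded from TP/FN/FP but
#' count in the safety-coverage denominator (coverage is a pure sequence
#' fraction, stability is annotation-dependent).
#'
#' @param intervals data frame of safe intervals on the sequence, 0-based
#'   half-open, columns `start`, `end` (a windows tibble's `b_start`/
#'   `b_end` renamed, or any interval table).
#' @param annotation a [read_structure_annotation()] tibble (already
#'   filtered to this sequence, or carrying an `id` column with
#'   `seq_id` given).
#' @param seq_len sequence length.
#' @param seq_id optional sequence ID used to filter `annotation`.
#' @return one-row tibble: `tp`, `fn`, `fp`, `n_safe`, `n_stable`,
#'   `n_annotated`, `seq_len`, `safety_coverage`, `stable_coverage`.
#' @export
classify_positions <- function(intervals, annotation, seq_len,
                               seq_id = NULL) {
  stopifnot(seq_len >= 0)
  if (!is.null(seq_id) && "id" %in% names(annotation)) {
    annotation <- annotation[annotation$id == seq_id, ]
  }
  if (nrow(intervals)) {
    stopifnot(all(intervals$start >= 0), all(intervals$end <= seq_len),
              all(intervals$start <= intervals$end))
  }
  safe <- .interval_mask(intervals$start, intervals$end, seq_len)
  stopifnot(all(annotation$pos >= 0), all(annotation$pos < seq_len))
  annotated <- logical(seq_len)
  annotated[annotation$pos + 1L] <- TRUE
  stable <- logical(seq_len)
  stable[annotation$pos[annotation$stable] + 1L] <- TRUE
  tp <- sum(safe & stable)
  fn <- sum(!safe & stable)
  fp <- sum(safe & !stable & annotated)
  tibble::tibble(
    tp = tp, fn = fn, fp = fp,
    n_safe = sum(safe), n_stable = sum(stable),
    n_annotated = sum(annotated), seq_len = seq_len,
    safety_coverage = if (seq_len > 0) sum(safe) / seq_len else NA_real_,
    stable_coverage = if (seq_len > 0) sum(stable) / seq_len else NA_real_)
}

#' Retention, overlap and F1 from confusion counts
#'
#' Undefined ratios (zero denominators) are reported as `NA`, not 0.
#'
#' @param counts a [classify_positions()] tibble (any number of rows).
#' @return the input with `retention`, `overlap` and `f1` columns added.
#' @examples
#' summary_metrics(tibble::tibble(tp = 2, fn = 2, fp = 2))
#' @export
summary_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- dplyr::mutate(counts,
                       retention = ratio(tp, tp + fn),
                       overlap = ratio(tp, tp + fp))
  dplyr::mutate(out,
                f1 = ifelse(!is.na(retention) & !is.na(overlap) &
                              (retention + overlap) > 0,
                            2 * retention * overlap / (retention + overlap),
                            NA_real_))
}

#' Structure-retention report for a cluster fit
#'
#' One row per member sequence: pairwise identity of the deterministic
#' optimal alignment against the representative, window summary, coverage
#' and the retention/overlap/F1 metrics of the member-side window
#' projections against the member's stable-structure labels.
#'
#' @param fit a [cluster_safety()] result.
#' @param annotation a [read_structure_annotation()] tibble with member
#'   IDs in its `id` column.
#' @return tibble: `id`, `identity`, `n_windows`, `mean_window_length`,
#'   `safety_coverage`, `stable_coverage`, `tp`, `fn`, `fp`, `retention`,
#'   `overlap`, `f1`.
#' @export
safety_report <- function(fit, annotation) {
  stopifnot(inherits(fit, "cluster_safety"))
  rows <- lapply(names(fit$results), function(member) {
    pair <- fit$results[[member]]
    w <- pair$windows
    counts <- classify_positions(
      tibble::tibble(start = w$b_start, end = w$b_end),
      annotation, pair$m, seq_id = member)
    aln <- optimal_alignment(pair$seq_a, pair$seq_b, fit$scoring)
    dplyr::bind_cols(
      tibble::tibble(id = member, identity = aln$identity,
                     n_windows = nrow(w),
                     mean_window_length =
                       if (nrow(w)) mean(w$b_end - w$b_start) else NA_real_),
      summary_metrics(counts))
  })
  dplyr::bind_rows(rows)
}
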