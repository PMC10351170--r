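#' Safety windows for every member of a sequence cluster
#'
#' Aligns each cluster member against the representative and computes its
#' (alpha, Delta)-safety windows; a k-sequence cluster yields k - 1 window
#' sets.  Pairs are independent, so the result does not depend on
#' evaluation order.
#'
#' @param cluster a [read_cluster_fasta()] result (or list with
#'   `representative` and `members` named character vectors).
#' @inheritParams align_safety
#' @return object of class `cluster_safety`: `representative`, named list
#'   `results` of [align_safety()] fits, and the parameters.
#' @export
cluster_safety <- function(cluster, scoring = scoring_scheme(),
                           alpha = 0.75, delta = 8, merge = FALSE) {
  stopifnot(!is.null(cluster$representative))
  members <- cluster$members
  results <- lapply(stats::setNames(names(members), names(members)),
                    function(id) {
                      align_safety(unname(cluster$representative),
                                   unname(members[[id]]),
                                   scoring, alpha, delta, merge)
                    })
  structure(list(representative = cluster$representative,
                 results = results, alpha = alpha, delta = delta,
                 merge = merge, scoring = scoring),
            class = "cluster_safety")
}

#' @export
print.cluster_safety <- function(x, ...) {
  cat("<cluster_safety> representative '", names(x$representative), "', ",
      length(x$results), " member pairs, alpha = ", x$alpha, ", delta = ",
      x$delta, "\n", sep = "")
  invisible(x)
}

#' Combined window table of a cluster fit
#'
#' @param x a [cluster_safety()] result.
#' @param ... unused.
#' @return tibble with one row per window across all member pairs; columns
#'   match [read_safety_windows()] so that a written native file
#'   round-trips to this table.
#' @export
tidy.cluster_safety <- function(x, ...) {
  rep_id <- names(x$representative)
  rows <- lapply(names(x$results), function(member) {
    fit <- x$results[[member]]
    w <- tidy(fit)
    if (!nrow(w)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(member = member, representative = rep_id,
                     alpha = fit$alpha, delta = fit$delta, opt = fit$opt,
                     .rows = nrow(w)),
      w[, c("window", "i1", "j1", "i2", "j2", "a_start", "a_end",
            "b_start", "b_end", "proportion", "proportion_exact", "merged")])
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- .empty_window_table()
  out
}

#' Per-member summary of a cluster fit
#'
#' @param x a [cluster_safety()] result.
#' @param ... unused.
#' @return tibble with one row per member: glance columns of each pair fit.
#' @export
glance.cluster_safety <- function(x, ...) {
  rows <- lapply(names(x$results), function(member) {
    dplyr::bind_cols(tibble::tibble(member = member),
                     glance(x$results[[member]]))
  })
  dplyr::bind_rows(rows)
}
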