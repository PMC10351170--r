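# Cluster FASTA input, per-residue structure annotations, and the
# safety-window output formats (native text, JSON, BED).

#' Read a protein sequence cluster from FASTA
#'
#' The first record is the cluster representative unless
#' `representative_id` names another record, which is then moved to the
#' representative slot.  For a cluster of k sequences the downstream
#' pipeline produces k - 1 safety-window sets (representative vs each
#' member).
#'
#' @param path FASTA file with >= 1 records and unique IDs.
#' @param representative_id optional record ID to use as representative.
#' @return object of class `seq_cluster`: `representative` (named string),
#'   `members` (named character vector), `source`.
#' @export
read_cluster_fasta <- function(path, representative_id = NULL) {
  stopifnot(file.exists(path))
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("not a readable FASTA file: ",
                                            path, " (", conditionMessage(e),
                                            ")"))
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate record IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chars <- stats::setNames(as.character(seqs), ids)
  rep_idx <- 1L
  if (!is.null(representative_id)) {
    rep_idx <- match(representative_id, ids)
    if (is.na(rep_idx)) {
      stop("representative ID '", representative_id, "' not found in ", path)
    }
  }
  if (length(chars) == 1L) {
    warning("cluster has a single record; no pairs to align")
  }
  structure(list(representative = chars[rep_idx],
                 members = chars[-rep_idx], source = path),
            class = "seq_cluster")
}

#' @export
print.seq_cluster <- function(x, ...) {
  cat("<seq_cluster> representative '", names(x$representative), "' (",
      nchar(x$representative), " aa) + ", length(x$members), " members\n",
      sep = "")
  invisible(x)
}

#' Write a cluster back to FASTA (representative first)
#'
#' @param cluster a `seq_cluster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_fasta <- function(cluster, path) {
  stopifnot(inherits(cluster, "seq_cluster"))
  seqs <- c(cluster$representative, cluster$members)
  lines <- character(0)
  for (k in seq_along(seqs)) {
    lines <- c(lines, paste0(">", names(seqs)[k]), unname(seqs[k]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Project safety windows onto both sequences
#'
#' Window endpoints are between-characters node coordinates: the interval
#' `[x, y]` covers residues `x .. y-1` (0-based) and `[x, x]` is empty.  A
#' window `[(i1,j1), (i2,j2)]` therefore projects to `[i1, i2]` on the
#' representative A and `[j1, j2]` on the member B; a window spanning a gap
#' can have an empty projection on one side (e.g. the first gap of
#' aligning "AB" to "BC" as "AB-"/"-BC" gives window `[(0,0),(1,0)]`,
#' projecting to `[0, 1]` on A and the empty `[0, 0]` on B).
#'
#' @param windows data frame with columns `i1, j1, i2, j2` (window
#'   endpoints), e.g. a [compute_safety_windows()] tibble.
#' @return the input tibble with (re)computed `a_start, a_end, b_start,
#'   b_end` columns.
#' @export
project_window <- function(windows) {
  windows <- tibble::as_tibble(windows)
  stopifnot(all(c("i1", "j1", "i2", "j2") %in% names(windows)))
  with(windows, stopifnot(all(i1 <= i2), all(j1 <= j2),
                          all(i1 >= 0), all(j1 >= 0)))
  dplyr::mutate(windows, a_start = i1, a_end = i2,
                b_start = j1, b_end = j2)
}

#' Read a per-residue secondary-structure annotation table
#'
#' Tab-separated table with header columns `id`, `pos` (0-based residue
#' position) and `type` (a Stride secondary-structure type).  Residues of
#' type Coil, Strand or Turn are labeled not stable; all other types
#' (AlphaHelix, 310Helix, PiHelix, Bridge) are stable.  Such tables are
#' easily derived from Stride ASG records (id, residue number - 1, long
#' type name).
#'
#' @param path TSV file.
#' @return tibble `id`, `pos`, `type`, `stable`.
#' @export
read_structure_annotation <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  if (!all(c("id", "pos", "type") %in% names(df))) {
    stop("annotation table must have columns id, pos, type")
  }
  bad <- setdiff(unique(df$type), .STRIDE_TYPES)
  if (length(bad)) {
    stop("unknown structure type(s) ", paste0("'", bad, "'", collapse = ", "),
         "; legal values: ", paste(.STRIDE_TYPES, collapse = ", "))
  }
  if (anyDuplicated(df[, c("id", "pos")])) {
    stop("annotation table has more than one record for some position")
  }
  tibble::tibble(id = df$id, pos = df$pos, type = df$type,
                 stable = !(df$type %in% .UNSTABLE_TYPES))
}

.STRIDE_TYPES <- c("AlphaHelix", "310Helix", "PiHelix", "Strand", "Bridge",
                   "Coil", "Turn")
.UNSTABLE_TYPES <- c("Coil", "Strand", "Turn")

#' Write a structure annotation table
#'
#' @param annotation tibble with `id`, `pos`, `type` (and optionally
#'   `stable`, which is recomputed on read).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_structure_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("id", "pos", "type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- safety-window output -------------------------------------------------

.windows_for_output <- function(results) {
  if (inherits(results, "safety_alignment")) {
    results <- structure(list(representative = c(A = results$seq_a),
                              results = stats::setNames(list(results), "B")),
                         class = "cluster_safety")
  }
  stopifnot(inherits(results, "cluster_safety"))
  results
}

#' Write safety windows to file
#'
#' `native` is a documented plain-text block format: one block per member
#' pair with a `>`-header (member ID, representative ID, alpha, delta,
#' optimal score, window count) followed by one tab-separated line per
#' window (endpoints, projections, the double proportion in full `%.17g`
#' precision, the exact proportion truncated to 9 decimals, merged flag).
#' It round-trips losslessly through [read_safety_windows()].  `json` mirrors
#' the same content via jsonlite; `bed` emits 0-based half-open residue
#' intervals per sequence (one line per window and sequence, skipping empty
#' projections).
#'
#' @param results a [cluster_safety()] result (or single
#'   [align_safety()] fit).
#' @param path output file.
#' @param format one of `"native"`, `"json"`, `"bed"`.
#' @return `path`, invisibly.
#' @export
write_safety_windows <- function(results, path,
                                 format = c("native", "json", "bed")) {
  format <- match.arg(format)
  cl <- .windows_for_output(results)
  rep_id <- names(cl$representative)
  if (format == "native") {
    lines <- "# alignsafe safety-windows v1"
    for (member in names(cl$results)) {
      fit <- cl$results[[member]]
      w <- fit$windows
      lines <- c(lines, paste(
        paste0(">", member), rep_id,
        paste0("alpha=", format(fit$alpha, digits = 15)),
        paste0("delta=", fit$delta),
        paste0("opt=", fit$opt),
        paste0("windows=", nrow(w)), sep = "\t"))
      if (nrow(w)) {
        lines <- c(lines, paste(w$i1, w$j1, w$i2, w$j2,
                                w$a_start, w$a_end, w$b_start, w$b_end,
                                sprintf("%.17g", w$proportion),
                                w$proportion_exact,
                                as.integer(w$merged), sep = "\t"))
      }
    }
    writeLines(lines, path)
  } else if (format == "json") {
    obj <- list(format = "alignsafe-safety-windows", version = 1L,
                representative = rep_id,
                pairs = lapply(names(cl$results), function(member) {
                  fit <- cl$results[[member]]
                  list(member = member, alpha = fit$alpha, delta = fit$delta,
                       opt = fit$opt, n_paths = fit$n_paths,
                       windows = fit$windows[, c(
                         "window", "i1", "j1", "i2", "j2", "a_start",
                         "a_end", "b_start", "b_end", "proportion",
                         "proportion_exact", "merged")])
                }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- character(0)
    for (member in names(cl$results)) {
      fit <- cl$results[[member]]
      w <- fit$windows
      for (r in seq_len(nrow(w))) {
        nm <- paste0(member, "_w", w$window[r])
        if (w$a_end[r] > w$a_start[r]) {
          lines <- c(lines, paste(rep_id, w$a_start[r], w$a_end[r], nm,
                                  sep = "\t"))
        }
        if (w$b_end[r] > w$b_start[r]) {
          lines <- c(lines, paste(member, w$b_start[r], w$b_end[r], nm,
                                  sep = "\t"))
        }
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read native-format safety windows
#'
#' Inverse of [write_safety_windows()]'s native format.
#'
#' @param path native safety-window file.
#' @return tibble with one row per window: `member`, `representative`,
#'   `alpha`, `delta`, `opt`, `window`, endpoints, projections,
#'   `proportion`, `proportion_exact`, `merged`. Header-only blocks
#'   (windowless pairs) contribute zero rows but are recorded in the
#'   `pairs` attribute.
#' @export
read_safety_windows <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- list()
  pairs <- list()
  hdr <- NULL
  widx <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      f <- strsplit(sub("^>", "", ln), "\t", fixed = TRUE)[[1]]
      hdr <- list(member = f[1], representative = f[2],
                  alpha = as.numeric(sub("alpha=", "", f[3])),
                  delta = as.numeric(sub("delta=", "", f[4])),
                  opt = as.numeric(sub("opt=", "", f[5])),
                  windows = as.integer(sub("windows=", "", f[6])))
      pairs[[length(pairs) + 1L]] <- hdr
      widx <- 0L
    } else {
      if (is.null(hdr)) stop("malformed file: window line before any header")
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      widx <- widx + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        member = hdr$member, representative = hdr$representative,
        alpha = hdr$alpha, delta = hdr$delta, opt = hdr$opt,
        window = widx,
        i1 = as.integer(f[1]), j1 = as.integer(f[2]),
        i2 = as.integer(f[3]), j2 = as.integer(f[4]),
        a_start = as.integer(f[5]), a_end = as.integer(f[6]),
        b_start = as.integer(f[7]), b_end = as.integer(f[8]),
        proportion = as.numeric(f[9]), proportion_exact = f[10],
        merged = as.integer(f[11]) == 1L)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else .empty_window_table()
  attr(out, "pairs") <- dplyr::bind_rows(lapply(pairs, tibble::as_tibble))
  out
}

.empty_window_table <- function() {
  tibble::tibble(
    member = character(), representative = character(), alpha = numeric(),
    delta = numeric(), opt = numeric(), window = integer(), i1 = integer(),
    j1 = integer(), i2 = integer(), j2 = integer(), a_start = integer(),
    a_end = integer(), b_start = integer(), b_end = integer(),
    proportion = numeric(), proportion_exact = character(),
    merged = logical())
}
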