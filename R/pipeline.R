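# End-to-end per-cluster workflow: FASTA in, safety windows (and optional
# structure-retention metrics) out.  The exec/alignsafe script is a thin
# command-line wrapper over run_safety_pipeline().

#' Run the safety-window pipeline on a cluster FASTA
#'
#' Reads the cluster, aligns every member against the representative,
#' computes (alpha, Delta)-safety windows and writes them in the requested
#' format; with an annotation table it also writes a structure-retention
#' metrics TSV.  Same inputs and parameters give byte-identical outputs.
#'
#' @param input cluster FASTA file, or a directory of FASTA files
#'   (processed independently, sorted by name).
#' @param outdir output directory (created if missing).
#' @inheritParams align_safety
#' @param gap_open,gap_extend affine gap parameters (non-positive
#'   integers).
#' @param matrix substitution matrix: builtin name or file path.
#' @param representative optional representative record ID.
#' @param format output format: `"native"`, `"json"` or `"bed"`.
#' @param annotation optional structure-annotation TSV path; triggers the
#'   metrics report.
#' @param quiet suppress progress messages (written to stderr).
#' @return invisibly, a tibble with one row per processed cluster file and
#'   columns `input`, `windows_file`, `metrics_file`, `n_pairs`,
#'   `n_windows`.
#' @export
run_safety_pipeline <- function(input, outdir, alpha = 0.75, delta = 8,
                                gap_open = -11, gap_extend = -1,
                                matrix = "BLOSUM62", representative = NULL,
                                merge = FALSE,
                                format = c("native", "json", "bed"),
                                annotation = NULL, quiet = FALSE) {
  format <- match.arg(format)
  .check_alpha(alpha)
  if (length(delta) != 1L || is.na(delta) || delta < 0 ||
      (is.finite(delta) && delta != floor(delta))) {
    stop("`delta` must be a single nonnegative integer")
  }
  if (!file.exists(input)) stop("input path does not exist: ", input)
  files <- if (dir.exists(input)) {
    sort(list.files(input, pattern = "\\.(fa|fasta|faa)$", full.names = TRUE))
  } else input
  if (!length(files)) stop("no FASTA files found under ", input)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scoring <- scoring_scheme(matrix, gap_open, gap_extend)
  ann <- if (!is.null(annotation)) read_structure_annotation(annotation)
  say <- function(...) if (!quiet) message(...)
  ext <- c(native = "safety.txt", json = "safety.json", bed = "safety.bed")
  rows <- lapply(files, function(f) {
    cluster <- read_cluster_fasta(f, representative)
    say("cluster ", f, ": representative '", names(cluster$representative),
        "', ", length(cluster$members), " members")
    fit <- cluster_safety(cluster, scoring, alpha, delta, merge)
    for (member in names(fit$results)) {
      pair <- fit$results[[member]]
      say("  ", member, ": opt=", pair$opt, " paths=", pair$n_paths,
          " windows=", nrow(pair$windows))
    }
    base <- sub("\\.[^.]*$", "", basename(f))
    wfile <- file.path(outdir, paste0(base, ".", ext[[format]]))
    write_safety_windows(fit, wfile, format)
    mfile <- NA_character_
    if (!is.null(ann)) {
      mfile <- file.path(outdir, paste0(base, ".metrics.tsv"))
      rep <- safety_report(fit, ann)
      utils::write.table(rep, mfile, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    tibble::tibble(input = f, windows_file = wfile, metrics_file = mfile,
                   n_pairs = length(fit$results),
                   n_windows = sum(vapply(fit$results,
                                          function(p) nrow(p$windows), 0L)))
  })
  invisible(dplyr::bind_rows(rows))
}
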