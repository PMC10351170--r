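#' Scoring scheme for global protein alignment
#'
#' Bundles an integer substitution matrix with affine gap parameters.  A gap
#' of length \eqn{\ell} scores \eqn{p + \ell g} where `gap_open` = p and
#' `gap_extend` = g (both non-positive integers).  The default matrix is
#' BLOSUM62 in the standard NCBI 24-symbol layout, bundled with the package.
#'
#' @param matrix integer substitution matrix with identical row and column
#'   symbol names, a builtin matrix name (currently `"BLOSUM62"`), or a path
#'   to an NCBI-format matrix file.
#' @param gap_open gap opening score p (<= 0, integer). Default -11.
#' @param gap_extend gap extension score g (<= 0, integer). Default -1.
#' @param wildcard score assigned to residue pairs involving a symbol absent
#'   from the matrix alphabet, or `NULL` to treat unknown residues as an
#'   error. Default -4 (the BLOSUM62 `*` penalty).
#' @return object of class `scoring_scheme` with elements `matrix`,
#'   `gap_open`, `gap_extend`, `alphabet`, `wildcard`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["A", "A"]   # 4
#' sc$matrix["W", "W"]   # 11
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -11L,
                           gap_extend = -1L, wildcard = -4L) {
  if (is.character(matrix)) matrix <- read_substitution_matrix(matrix)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix))) {
    stop("substitution matrix must carry identical row and column symbols")
  }
  if (any(matrix != floor(matrix))) stop("substitution scores must be integers")
  if (length(gap_open) != 1L || gap_open > 0 || gap_open != floor(gap_open)) {
    stop("`gap_open` must be a single non-positive integer")
  }
  if (length(gap_extend) != 1L || gap_extend > 0 ||
      gap_extend != floor(gap_extend)) {
    stop("`gap_extend` must be a single non-positive integer")
  }
  if (!is.null(wildcard)) stopifnot(length(wildcard) == 1L,
                                    wildcard == floor(wildcard))
  structure(
    list(matrix = matrix, gap_open = as.numeric(gap_open),
         gap_extend = as.numeric(gap_extend),
         alphabet = rownames(matrix),
         wildcard = if (is.null(wildcard)) NULL else as.numeric(wildcard)),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", length(x$alphabet), " symbols; gap open ",
      x$gap_open, ", extend ", x$gap_extend, "\n", sep = "")
  invisible(x)
}

#' Read a substitution matrix in NCBI text layout
#'
#' Parses the whitespace-separated matrix format used by NCBI tools: an
#' optional block of `#` comment lines, a header row of symbols, then one
#' row per symbol starting with its symbol.  `"BLOSUM62"` names the bundled
#' copy of the standard matrix.
#'
#' @param x builtin matrix name or file path.
#' @return integer matrix with symbol dimnames.
#' @export
read_substitution_matrix <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (toupper(x) == "BLOSUM62") {
    x <- system.file("extdata", "BLOSUM62.txt", package = "alignsafe",
                     mustWork = TRUE)
  }
  if (!file.exists(x)) stop("substitution matrix file not found: ", x)
  lines <- readLines(x)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("matrix file has no data rows: ", x)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  sigma <- length(header)
  if (length(lines) - 1L != sigma) {
    stop("matrix file declares ", sigma, " symbols but has ",
         length(lines) - 1L, " data rows")
  }
  M <- matrix(NA_real_, sigma, sigma, dimnames = list(header, header))
  for (r in seq_len(sigma)) {
    fields <- strsplit(trimws(lines[r + 1L]), "\\s+")[[1]]
    if (length(fields) != sigma + 1L) {
      stop("line ", lineno[r + 1L], ": row '", fields[1], "' has ",
           length(fields) - 1L, " cells, expected ", sigma)
    }
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals) || any(vals != floor(vals))) {
      stop("line ", lineno[r + 1L], ": non-integer cell in row '",
           fields[1], "'")
    }
    M[fields[1], ] <- vals
  }
  if (!setequal(rownames(M), header) || anyNA(M)) {
    stop("matrix row symbols do not match the header symbols")
  }
  M[header, header, drop = FALSE]
}

# integer-encode a residue string against a scoring scheme; unknown symbols
# either extend the matrix with the wildcard score or raise an error naming
# the offending symbol and its 1-based position
.encode_sequence <- function(seq, scoring, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  unknown <- !(chars %in% scoring$alphabet)
  if (any(unknown) && is.null(scoring$wildcard)) {
    i <- which(unknown)[1]
    stop("residue '", chars[i], "' at position ", i, " of ", what,
         " is not in the scoring alphabet and no wildcard score is set")
  }
  chars
}

# full score lookup including wildcard extension
.score_matrix_for <- function(scoring, chars_a, chars_b) {
  extra <- setdiff(unique(c(chars_a, chars_b)), scoring$alphabet)
  M <- scoring$matrix
  if (length(extra)) {
    syms <- c(scoring$alphabet, extra)
    M2 <- matrix(scoring$wildcard, length(syms), length(syms),
                 dimnames = list(syms, syms))
    M2[scoring$alphabet, scoring$alphabet] <- M
    M <- M2
  }
  M
}
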