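# Exact nonnegative big-integer arithmetic on base-1e6 limb vectors.
#
# Path counts in the suboptimal alignment graph grow like the Delannoy
# numbers (~5.8^n), far beyond the 2^53 exact-integer range of doubles, and
# all safety decisions must be exact rational comparisons.  Limbs are stored
# little-endian in a plain numeric vector; every limb is an integer in
# [0, 1e6).  With base 1e6 a schoolbook product limb is < 1e12 and sums of a
# few thousand such products stay well below 2^53, so doubles are exact
# throughout.

.BI_BASE <- 1e6

#' Construct a big integer from a nonnegative double
#'
#' @param x nonnegative integer-valued double below 2^53.
#' @return limb vector (class `bigint`), little-endian base 1e6.
#' @keywords internal
bi <- function(x) {
  stopifnot(length(x) == 1L, !is.na(x), x >= 0, x == floor(x))
  if (x == 0) return(structure(numeric(0), class = "bigint"))
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% .BI_BASE)
    x <- floor(x / .BI_BASE)
  }
  structure(limbs, class = "bigint")
}

bi_is_zero <- function(a) length(a) == 0L

.bi_norm <- function(limbs) {
  # carry-normalise, then strip high zero limbs
  carry <- floor(limbs / .BI_BASE)
  while (any(carry > 0)) {
    limbs <- limbs - carry * .BI_BASE
    limbs <- c(limbs, 0) + c(0, carry)
    carry <- floor(limbs / .BI_BASE)
  }
  n <- length(limbs)
  while (n > 0L && limbs[n] == 0) n <- n - 1L
  structure(limbs[seq_len(n)], class = "bigint")
}

bi_add <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L) return(b)
  if (lb == 0L) return(a)
  n <- max(la, lb)
  s <- c(unclass(a), numeric(n - la)) + c(unclass(b), numeric(n - lb))
  .bi_norm(s)
}

# a - b, requires a >= b
bi_sub <- function(a, b) {
  la <- length(a); lb <- length(b)
  stopifnot(lb <= la)
  if (lb == 0L) return(a)
  d <- c(unclass(a)) - c(unclass(b), numeric(la - lb))
  # borrow propagation
  i <- 1L
  while (i <= la) {
    if (d[i] < 0) {
      d[i] <- d[i] + .BI_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
    i <- i + 1L
  }
  n <- la
  while (n > 0L && d[n] == 0) n <- n - 1L
  structure(d[seq_len(n)], class = "bigint")
}

bi_mul <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(structure(numeric(0), class = "bigint"))
  # accumulated limbs stay < min(la, lb) * 1e12; exact in doubles up to
  # ~9000 limbs, orders of magnitude beyond any count arising here
  stopifnot(min(la, lb) < 8000L)
  if (la > lb) { tmp <- a; a <- b; b <- tmp; la <- length(a); lb <- length(b) }
  res <- numeric(la + lb)
  ua <- unclass(a); ub <- unclass(b)
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1L)
    res[idx] <- res[idx] + ua[i] * ub
  }
  .bi_norm(res)
}

#' Compare two big integers: -1, 0 or 1
#' @keywords internal
bi_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  if (la == 0L) return(0L)
  for (i in la:1) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

bi_eq <- function(a, b) bi_cmp(a, b) == 0L

#' Decimal string of a big integer
#' @keywords internal
bi_to_char <- function(a) {
  if (bi_is_zero(a)) return("0")
  n <- length(a)
  parts <- sprintf("%06d", as.integer(rev(unclass(a))))
  parts[1] <- as.character(as.numeric(parts[1]))
  paste(parts, collapse = "")
}

#' Approximate double value (may overflow to Inf for huge integers)
#' @keywords internal
bi_to_num <- function(a) {
  if (bi_is_zero(a)) return(0)
  sum(unclass(a) * .BI_BASE^(seq_along(a) - 1))
}

#' Exact decimal expansion of num/den, truncated to `digits` fractional digits
#'
#' Used to print exact path proportions. Requires 0 <= num <= den, den > 0.
#' Long division: each digit is found with at most nine subtract/compare
#' steps, so no big-integer division routine is needed.
#' @keywords internal
bi_ratio_decimal <- function(num, den, digits = 9L) {
  stopifnot(!bi_is_zero(den), bi_cmp(num, den) <= 0L)
  if (bi_cmp(num, den) == 0L) {
    return(paste0("1.", strrep("0", digits)))
  }
  r <- num
  out <- character(digits)
  ten <- bi(10)
  for (k in seq_len(digits)) {
    r <- bi_mul(r, ten)
    d <- 0L
    while (bi_cmp(r, den) >= 0L) {
      r <- bi_sub(r, den)
      d <- d + 1L
    }
    out[k] <- as.character(d)
  }
  paste0("0.", paste(out, collapse = ""))
}

#' Exact rational proportion
#'
#' Lightweight container for an exact ratio num/den of big integers, as
#' produced by [edge_proportion()] and [path_proportion()].
#'
#' @param num,den big integers (`bigint`), 0 <= num/den <= 1.
#' @return object of class `exact_ratio`.
#' @keywords internal
exact_ratio <- function(num, den) {
  structure(list(num = num, den = den), class = "exact_ratio")
}

#' @export
as.double.exact_ratio <- function(x, ...) {
  v <- bi_to_num(x$num) / bi_to_num(x$den)
  if (is.nan(v) || is.infinite(v)) {
    # fall back to exact decimal digits when doubles overflow
    v <- as.numeric(bi_ratio_decimal(x$num, x$den, 15L))
  }
  v
}

#' @export
format.exact_ratio <- function(x, digits = 9L, ...) {
  bi_ratio_decimal(x$num, x$den, digits)
}

#' @export
print.exact_ratio <- function(x, ...) {
  cat("<exact_ratio> ", format(x), " (", bi_to_char(x$num), "/",
      bi_to_char(x$den), ")\n", sep = "")
  invisible(x)
}

# alpha >= 0.5 thresholds arrive as decimals like 0.51, 0.75, 1; convert the
# printed decimal to an exact small-integer fraction.
.alpha_rational <- function(alpha) {
  if (is.character(alpha) && grepl("/", alpha, fixed = TRUE)) {
    parts <- as.numeric(strsplit(alpha, "/", fixed = TRUE)[[1]])
    stopifnot(length(parts) == 2L, all(parts == floor(parts)), parts[2] > 0)
    return(list(num = parts[1], den = parts[2]))
  }
  alpha <- as.numeric(alpha)
  s <- format(alpha, digits = 15, scientific = FALSE)
  if (!grepl(".", s, fixed = TRUE)) return(list(num = alpha, den = 1))
  frac <- sub("^[^.]*\\.", "", s)
  den <- 10^nchar(frac)
  list(num = round(alpha * den), den = den)
}
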