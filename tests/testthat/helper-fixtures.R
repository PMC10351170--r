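# shared fixtures: tiny scoring schemes and seeded random sequences

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

blosum <- function(gap_open = -11, gap_extend = -1) {
  scoring_scheme("BLOSUM62", gap_open, gap_extend)
}

# two-symbol toy matrix: match +2, mismatch -1
toy_scoring <- function(gap_open = -3, gap_extend = -1) {
  M <- matrix(c(2, -1, -1, 2), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  scoring_scheme(M, gap_open, gap_extend, wildcard = NULL)
}

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# engine windows for a sequence pair, plus the intermediate objects
fit_pair <- function(a, b, scoring, alpha, delta) {
  g <- build_alignment_graph(a, b, scoring)
  sg <- extract_delta_subgraph(g, compute_score_tables(g), delta)
  counts <- count_paths(sg)
  list(graph = g, subgraph = sg, counts = counts,
       windows = compute_safety_windows(sg, alpha, counts = counts))
}

expect_windows_equal_oracle <- function(eng, orc) {
  expect_equal(nrow(eng), nrow(orc))
  if (nrow(orc) == 0) return(invisible())
  expect_equal(eng$i1, orc$i1)
  expect_equal(eng$j1, orc$j1)
  expect_equal(eng$i2, orc$i2)
  expect_equal(eng$j2, orc$j2)
  # proportions: exact-decimal equality (both are the same rational
  # truncated to 9 digits) plus the double view
  orc_exact <- vapply(seq_len(nrow(orc)), function(r)
    alignsafe:::bi_ratio_decimal(alignsafe:::bi(orc$prop_num[r]),
                                 alignsafe:::bi(orc$prop_den[r]), 9L), "")
  expect_equal(eng$proportion_exact, orc_exact)
  expect_equal(eng$proportion, orc$proportion, tolerance = 1e-12)
}

# node labels, robust to zero-length inputs (paste0 would recycle literals)
node_keys <- function(layer, i, j) {
  if (length(layer) == 0L) return(character(0))
  paste0(layer, ":", i, ":", j)
}

# canonical key of an undirected node pair
undirected_keys <- function(u, v) {
  if (length(u) == 0L) return(character(0))
  paste(pmin(u, v), pmax(u, v), sep = "|")
}
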