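# safety-window engine: spanning path, two-pointer, merging

test_that("alpha outside (0.5, 1] is rejected", {
  sc <- blosum()
  f <- fit_pair("AR", "AR", sc, 1, 0)
  expect_error(compute_safety_windows(f$subgraph, 0.5), "0.5")
  expect_error(compute_safety_windows(f$subgraph, 0.4), "0.5")
  expect_error(compute_safety_windows(f$subgraph, 1.2), "0.5")
  expect_error(align_safety("AR", "AR", sc, alpha = 0.4), "0.5")
})

test_that("identical sequences under delta 0 give one full-span window", {
  sc <- blosum()
  w <- safety_windows("ARN", "ARN", sc, alpha = 1, delta = 0)
  expect_equal(nrow(w), 1L)
  expect_equal(unlist(w[1, c("i1", "j1", "i2", "j2")], use.names = FALSE),
               c(0L, 0L, 3L, 3L))
  expect_equal(w$proportion, 1)
  expect_equal(w$proportion_exact, "1.000000000")
})

test_that("windows match the exhaustive oracle on random instances", {
  sc <- blosum()
  set.seed(207)
  for (k in 1:40) {
    a <- rand_seq(sample(2:6, 1)); b <- rand_seq(sample(2:6, 1))
    delta <- sample(0:10, 1)
    alpha <- sample(c(0.51, 0.75, 1), 1)
    f <- fit_pair(a, b, sc, alpha, delta)
    orc <- oracle_safety_windows(a, b, sc, alpha, delta)
    expect_equal(f$counts$total_dbl, attr(orc, "n_paths"))
    expect_windows_equal_oracle(f$windows, orc)
  }
})

test_that("window proportions are >= alpha and one-node extensions fall below", {
  sc <- blosum()
  set.seed(52)
  for (k in 1:10) {
    a <- rand_seq(5); b <- rand_seq(6)
    alpha <- sample(c(0.51, 0.75), 1)
    delta <- sample(4:10, 1)
    f <- fit_pair(a, b, sc, alpha, delta)
    w <- f$windows
    pstar <- attr(w, "pstar")
    for (r in seq_len(nrow(w))) {
      expect_gte(w$proportion[r], alpha - 1e-12)
      if (w$L[r] > 1) {
        pl <- as.numeric(path_proportion(f$counts,
                                         pstar[(w$L[r] - 1):w$R[r], ]))
        expect_lt(pl, alpha)
      }
      if (w$R[r] < nrow(pstar)) {
        pr <- as.numeric(path_proportion(f$counts,
                                         pstar[w$L[r]:(w$R[r] + 1), ]))
        expect_lt(pr, alpha)
      }
    }
    # windows are ordered with strictly increasing span, none contains
    # another
    if (nrow(w) > 1) {
      expect_true(all(diff(w$L) > 0))
      expect_true(all(diff(w$R) > 0))
    }
  }
})

test_that("for alpha = 1 and delta = 0 the safe edges are the bridges of G_0", {
  skip_if_not_installed("igraph")
  sc <- blosum()
  set.seed(77)
  for (k in 1:50) {
    a <- rand_seq(sample(2:6, 1)); b <- rand_seq(sample(2:6, 1))
    f <- fit_pair(a, b, sc, 1, 0)
    ed <- subgraph_edges(f$subgraph)
    safe <- safe_edges(f$subgraph, f$counts, 1)
    gr <- igraph::graph_from_edgelist(
      cbind(paste0(ed$ulayer, ":", ed$ui, ":", ed$uj),
            paste0(ed$vlayer, ":", ed$vi, ":", ed$vj)),
      directed = FALSE)
    br <- igraph::bridges(gr)
    ends <- igraph::ends(gr, br)
    bridge_keys <- undirected_keys(ends[, 1], ends[, 2])
    safe_keys <- undirected_keys(node_keys(safe$ulayer, safe$ui, safe$uj),
                                 node_keys(safe$vlayer, safe$vi, safe$vj))
    expect_setequal(safe_keys, bridge_keys)
  }
})

test_that("alpha monotonicity: stricter windows nest inside looser ones", {
  sc <- blosum()
  set.seed(88)
  for (k in 1:15) {
    a <- rand_seq(sample(3:6, 1)); b <- rand_seq(sample(3:6, 1))
    delta <- sample(0:10, 1)
    w_hi <- safety_windows(a, b, sc, alpha = 1, delta = delta)
    w_lo <- safety_windows(a, b, sc, alpha = 0.51, delta = delta)
    for (r in seq_len(nrow(w_hi))) {
      contained <- any(w_lo$i1 <= w_hi$i1[r] & w_lo$j1 <= w_hi$j1[r] &
                         w_lo$i2 >= w_hi$i2[r] & w_lo$j2 >= w_hi$j2[r])
      expect_true(contained)
    }
  }
})

test_that("window merging joins intersecting or adjacent projections", {
  sc <- blosum()
  # an ambiguous two-residue insertion splits the safety windows at an
  # A-adjacent boundary: projections [0,3] and [3,10] touch on A
  a <- "PQQGTTKHWL"
  b <- "PQQNSGTTKHWL"
  f <- fit_pair(a, b, sc, 0.51, 6)
  w <- f$windows
  expect_equal(nrow(w), 2L)
  expect_lte(w$a_start[2], w$a_end[1])
  merged <- merge_windows(w, f$counts, attr(w, "pstar"))
  expect_equal(nrow(merged), 1L)
  expect_true(merged$merged)
  # merged window spans the union of both projections
  expect_equal(merged$a_start, min(w$a_start))
  expect_equal(merged$a_end, max(w$a_end))
  expect_equal(merged$b_start, min(w$b_start))
  expect_equal(merged$b_end, max(w$b_end))
  # proportion recomputed exactly over the spanned subpath; it may fall
  # below alpha
  pr <- path_proportion(f$counts, attr(w, "pstar")[merged$L:merged$R, ])
  expect_equal(merged$proportion, as.numeric(pr))
  expect_lte(merged$proportion, min(w$proportion))
  # the merge-at-fit interface flags the same result
  fit <- align_safety(a, b, sc, alpha = 0.51, delta = 6, merge = TRUE)
  expect_equal(tidy(fit)$merged, TRUE)
  # interval arithmetic of the grouping rule
  expect_equal(nrow(merge_windows(w, f$counts, attr(w, "pstar"))), 1L)
})

test_that("disjoint windows survive merging unchanged", {
  sc <- blosum()
  set.seed(52)
  a <- rand_seq(6); b <- rand_seq(6)
  f <- fit_pair(a, b, sc, 0.75, 6)
  w <- f$windows
  if (nrow(w) > 1 && all(w$a_start[-1] > w$a_end[-nrow(w)])) {
    merged <- merge_windows(w, f$counts, attr(w, "pstar"))
    expect_equal(merged$i1, w$i1)
    expect_false(any(merged$merged))
  }
  succeed()
})

test_that("empty and gap-only pairs behave", {
  sc <- blosum()
  w0 <- safety_windows("", "", sc, alpha = 1, delta = 0)
  expect_equal(nrow(w0), 0L)
  # one sequence empty: single forced gap path, full window on A only
  w1 <- safety_windows("AR", "", sc, alpha = 1, delta = 0)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$a_start, 0L)
  expect_equal(w1$a_end, 2L)
  expect_equal(w1$b_start, w1$b_end)
})
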