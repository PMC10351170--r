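# exact path counting, edge and path proportions

test_that("counts are symmetric and normalized", {
  sc <- blosum()
  set.seed(21)
  for (k in 1:10) {
    a <- rand_seq(sample(1:5, 1)); b <- rand_seq(sample(1:5, 1))
    delta <- sample(c(0, 4, 8, Inf), 1)
    g <- build_alignment_graph(a, b, sc)
    sg <- extract_delta_subgraph(g, compute_score_tables(g), delta)
    pc <- count_paths(sg)
    # d(s) == d_r(t)
    expect_equal(alignsafe:::bi_cmp(
      pc$dC[[1L, 1L]], pc$drC[[g$n + 1L, g$m + 1L]]), 0L)
    # sum of edge proportions over the source's out-edges == 1 exactly
    ed <- subgraph_edges(sg)
    out_s <- ed[ed$ulayer == "C" & ed$ui == 0 & ed$uj == 0, ]
    num <- alignsafe:::bi(0)
    for (r in seq_len(nrow(out_s))) {
      pr <- edge_proportion(pc, out_s[r, ])
      num <- alignsafe:::bi_add(num, pr$num)
      expect_true(identical(alignsafe:::bi_to_char(pr$den),
                            alignsafe:::bi_to_char(pc$total)))
    }
    expect_equal(alignsafe:::bi_cmp(num, pc$total), 0L)
  }
})

test_that("single-path subgraph proportions are 1", {
  sc <- blosum()
  f <- fit_pair("ARN", "ARN", sc, 1, 0)
  expect_equal(f$counts$total_dbl, 1)
  ed <- subgraph_edges(f$subgraph)
  for (r in seq_len(nrow(ed))) {
    expect_equal(as.numeric(edge_proportion(f$counts, ed[r, ])), 1)
  }
})

test_that("edge and path proportion contracts", {
  sc <- blosum()
  f <- fit_pair("ARN", "ARN", sc, 1, 0)
  expect_error(edge_proportion(f$counts,
                               list(type = "open_d", ui = 0L, uj = 0L)),
               "not in the subgraph")
  pstar <- attr(f$windows, "pstar")
  pr <- path_proportion(f$counts, pstar)
  expect_equal(as.numeric(pr), 1)
  # single node, Eq. 3 with k = 1
  pr1 <- path_proportion(f$counts, pstar[2, ])
  expect_equal(as.numeric(pr1), 1)
  # non-contiguous node selection is rejected
  expect_error(path_proportion(f$counts, pstar[c(1, 3), ]),
               "contiguous")
})

test_that("subpath proportion is monotone under extension", {
  sc <- blosum()
  set.seed(33)
  a <- rand_seq(5); b <- rand_seq(5)
  f <- fit_pair(a, b, sc, 0.51, 6)
  pstar <- attr(f$windows, "pstar")
  K <- nrow(pstar)
  for (L in 1:(K - 1)) {
    p_long <- as.numeric(path_proportion(f$counts, pstar[L:K, ]))
    p_short <- as.numeric(path_proportion(f$counts, pstar[(L + 1):K, ]))
    expect_lte(p_long, p_short + 1e-15)
  }
})

test_that("full-graph counts hit the Delannoy numbers in linear mode", {
  sc <- blosum()
  expect_equal(delannoy(0, 5), 1)
  expect_equal(delannoy(2, 2), 13)
  expect_equal(delannoy(3, 3), 63)
  g <- build_alignment_graph("ARND", "ARND", sc, gap_model = "linear")
  sg <- extract_delta_subgraph(g, compute_score_tables(g), Inf)
  expect_equal(count_paths(sg)$total_dbl, delannoy(4, 4))
})
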