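# alignment DAG construction, score tables and the Delta-subgraph

test_that("optimal scores match exhaustive enumeration on tiny pairs", {
  sc <- blosum()
  # "A" vs "A": 3 alignments (match; two double-gap configurations)
  aln <- enumerate_alignments("A", "A", sc, delta = Inf)
  expect_equal(nrow(aln), 3L)
  expect_equal(attr(aln, "opt"), 4)
  t <- compute_score_tables(build_alignment_graph("A", "A", sc))
  expect_equal(t$opt, 4)
  # identical triple: sum of diagonal scores
  t3 <- compute_score_tables(build_alignment_graph("ARN", "ARN", sc))
  expect_equal(t3$opt, 4 + 5 + 6)
  expect_equal(attr(enumerate_alignments("ARN", "ARN", sc, Inf), "opt"),
               t3$opt)
})

test_that("degenerate sequences follow the gap formula", {
  sc <- blosum()
  expect_equal(compute_score_tables(build_alignment_graph("A", "", sc))$opt,
               -11 - 1)
  expect_equal(compute_score_tables(build_alignment_graph("", "", sc))$opt, 0)
  expect_equal(compute_score_tables(
    build_alignment_graph("", "ARN", sc))$opt, -11 - 3)
})

test_that("optimal scores agree with an independent aligner", {
  skip_if_not_installed("Biostrings")
  sc <- blosum()
  set.seed(101)
  for (k in 1:25) {
    a <- rand_seq(sample(1:8, 1))
    b <- rand_seq(sample(1:8, 1))
    t <- compute_score_tables(build_alignment_graph(a, b, sc))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(t$opt, ref)
  }
})

test_that("prefix/suffix tables satisfy the edge optimality identity", {
  sc <- blosum()
  set.seed(5)
  a <- rand_seq(5); b <- rand_seq(6)
  g <- build_alignment_graph(a, b, sc)
  t <- compute_score_tables(g)
  sg0 <- extract_delta_subgraph(g, t, 0)
  ed <- subgraph_edges(sg0)
  for (r in seq_len(nrow(ed))) {
    pre <- switch(ed$ulayer[r], C = t$rc, D = t$rd, I = t$ri)[
      ed$ui[r] + 1L, ed$uj[r] + 1L]
    suf <- switch(ed$vlayer[r], C = t$wc, D = t$wd, I = t$wi)[
      ed$vi[r] + 1L, ed$vj[r] + 1L]
    expect_equal(pre + ed$weight[r] + suf, t$opt)
  }
})

test_that("graph size and delta validation", {
  sc <- blosum()
  g <- build_alignment_graph("AB", "BC", sc)
  expect_equal(g$n, 2L)
  expect_equal(g$m, 2L)
  t <- compute_score_tables(g)
  expect_error(extract_delta_subgraph(g, t, -1), "nonnegative")
  expect_error(extract_delta_subgraph(g, t, 1.5), "nonnegative")
})

test_that("delta subgraphs are nested and the identical-pair optimum is a single diagonal", {
  sc <- blosum()
  set.seed(9)
  for (k in 1:10) {
    a <- rand_seq(4); b <- rand_seq(4)
    g <- build_alignment_graph(a, b, sc)
    t <- compute_score_tables(g)
    s1 <- extract_delta_subgraph(g, t, 2)
    s2 <- extract_delta_subgraph(g, t, 7)
    for (mk in c("keep_m", "keep_od", "keep_oi", "keep_ed", "keep_ei",
                 "keep_cd", "keep_ci")) {
      expect_true(all(s2[[mk]][s1[[mk]]]))
    }
  }
  # unique optimum of an identical pair: diagonal path, one edge per residue
  g <- build_alignment_graph("AR", "AR", sc)
  sg <- extract_delta_subgraph(g, compute_score_tables(g), 0)
  ed <- subgraph_edges(sg)
  expect_equal(nrow(ed), 2L)
  expect_true(all(ed$type == "match"))
  expect_equal(count_paths(sg)$total_dbl, 1)
})

test_that("every kept edge lies on a Delta-suboptimal path", {
  sc <- blosum()
  set.seed(12)
  a <- rand_seq(4); b <- rand_seq(5)
  delta <- 6
  g <- build_alignment_graph(a, b, sc)
  t <- compute_score_tables(g)
  sg <- extract_delta_subgraph(g, t, delta)
  ed <- subgraph_edges(sg)
  # oracle: collect edges of all Delta-suboptimal layered paths
  paths <- alignsafe:::.enumerate_layer_paths(a, b, sc, delta)
  keys <- unique(unlist(lapply(paths, function(pp) {
    nd <- pp$nodes
    paste(nd[-length(nd)], nd[-1L], sep = ">")
  })))
  mine <- paste0(ed$ulayer, ":", ed$ui, ":", ed$uj, ">",
                 ed$vlayer, ":", ed$vi, ":", ed$vj)
  expect_setequal(mine, keys)
})

test_that("linear gap model collapses to the lattice bijection", {
  sc <- blosum()
  for (n in 0:4) {
    for (m in 0:4) {
      a <- paste(rep("A", n), collapse = "")
      b <- paste(rep("R", m), collapse = "")
      g <- build_alignment_graph(a, b, sc, gap_model = "linear")
      sg <- extract_delta_subgraph(g, compute_score_tables(g), Inf)
      expect_equal(count_paths(sg)$total_dbl, delannoy(n, m))
    }
  }
})
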