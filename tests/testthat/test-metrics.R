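# structure-retention metrics

full_annotation <- function(id, stable_pos, seq_len) {
  tibble::tibble(id = id, pos = 0:(seq_len - 1),
                 type = ifelse(0:(seq_len - 1) %in% stable_pos,
                               "AlphaHelix", "Coil"),
                 stable = 0:(seq_len - 1) %in% stable_pos)
}

test_that("per-residue confusion counts on hand-built fixtures", {
  # identity case: safe [0,5), stable {0..4}
  ann <- full_annotation("s", 0:4, 5)
  c1 <- classify_positions(tibble::tibble(start = 0, end = 5), ann, 5, "s")
  expect_equal(c(c1$tp, c1$fn, c1$fp), c(5, 0, 0))
  expect_equal(c1$safety_coverage, 1)
  # partial overlap: safe [0,4), stable {2..5}, length 8
  ann2 <- full_annotation("s", 2:5, 8)
  c2 <- classify_positions(tibble::tibble(start = 0, end = 4), ann2, 8, "s")
  expect_equal(c(c2$tp, c2$fn, c2$fp), c(2, 2, 2))
  # no safe intervals
  c3 <- classify_positions(tibble::tibble(start = integer(),
                                          end = integer()), ann2, 8, "s")
  expect_equal(c(c3$tp, c3$fp), c(0, 0))
  expect_equal(c3$fn, 4)
  expect_equal(c3$safety_coverage, 0)
  # out-of-bounds interval violates the contract
  expect_error(classify_positions(tibble::tibble(start = 0, end = 9),
                                  ann2, 8, "s"))
})

test_that("unannotated residues count for coverage but not confusion", {
  ann <- tibble::tibble(id = "s", pos = c(0L, 1L),
                        type = c("AlphaHelix", "Coil"),
                        stable = c(TRUE, FALSE))
  cc <- classify_positions(tibble::tibble(start = 0, end = 4), ann, 6, "s")
  expect_equal(c(cc$tp, cc$fp), c(1, 1))
  expect_equal(cc$safety_coverage, 4 / 6)
  expect_equal(cc$n_annotated, 2)
})

test_that("retention, overlap and F1 with absent-value semantics", {
  m <- summary_metrics(tibble::tibble(tp = 2, fn = 2, fp = 2))
  expect_equal(c(m$retention, m$overlap, m$f1), c(0.5, 0.5, 0.5))
  m2 <- summary_metrics(tibble::tibble(tp = 0, fn = 0, fp = 3))
  expect_true(is.na(m2$retention))
  expect_equal(m2$overlap, 0)
  m3 <- summary_metrics(tibble::tibble(tp = 5, fn = 0, fp = 0))
  expect_equal(c(m3$retention, m3$overlap, m3$f1), c(1, 1, 1))
  m4 <- summary_metrics(tibble::tibble(tp = 0, fn = 2, fp = 0))
  expect_true(is.na(m4$overlap))
  expect_true(is.na(m4$f1))
})

test_that("overlap beats stable coverage exactly when windows enrich", {
  ann <- full_annotation("s", c(0, 1, 2, 6), 10)
  cc <- summary_metrics(classify_positions(
    tibble::tibble(start = 0, end = 4), ann, 10, "s"))
  # (stable & safe)/safe vs stable/len: 3/4 > 4/10
  expect_gt(cc$overlap, cc$stable_coverage)
})

test_that("pairwise identity from the deterministic optimal traceback", {
  sc <- blosum()
  aln <- optimal_alignment("ARN", "ARN", sc)
  expect_equal(aln$identity, 1)
  expect_equal(aln$a_aln, "ARN")
  expect_equal(pairwise_identity(aln), 1)
  expect_equal(pairwise_identity(list(a_aln = "ARXY", b_aln = "ARZW")), 0.5)
  expect_equal(pairwise_identity(list(a_aln = "AR", b_aln = "ND")), 0)
  expect_true(is.na(pairwise_identity(list(a_aln = "", b_aln = ""))))
  # retention equals 1 whenever every stable residue is covered
  ann <- full_annotation("s", 2:3, 6)
  cc <- summary_metrics(classify_positions(
    tibble::tibble(start = 2, end = 5), ann, 6, "s"))
  expect_equal(cc$retention, 1)
})

test_that("cluster report wires identity, coverage and metrics together", {
  sc <- blosum()
  syn <- generate_cluster(n_members = 2, length = 20, sub_rate = 0.1,
                          indel_rate = 0, seed = 31)
  fit <- cluster_safety(syn$cluster, sc, alpha = 0.75, delta = 4)
  ann <- dplyr::bind_rows(lapply(names(syn$cluster$members), function(id)
    annotation_from_mask(syn$conserved, id)))
  rep <- safety_report(fit, ann)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$identity > 0.5))
  expect_true(all(rep$safety_coverage >= 0 & rep$safety_coverage <= 1))
  expect_true(all(is.na(rep$f1) | (rep$f1 >= 0 & rep$f1 <= 1)))
})
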