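# exact big-integer arithmetic against double arithmetic (exact below 2^53)
# and against algebraic identities at scales doubles cannot reach

bi <- alignsafe:::bi
bi_add <- alignsafe:::bi_add
bi_sub <- alignsafe:::bi_sub
bi_mul <- alignsafe:::bi_mul
bi_cmp <- alignsafe:::bi_cmp
bi_to_char <- alignsafe:::bi_to_char
bi_to_num <- alignsafe:::bi_to_num
bi_ratio_decimal <- alignsafe:::bi_ratio_decimal

test_that("limb arithmetic agrees with doubles on random values", {
  set.seed(1)
  for (k in 1:200) {
    x <- floor(stats::runif(1, 0, 1e12))
    y <- floor(stats::runif(1, 0, 1e12))
    expect_equal(bi_to_num(bi_add(bi(x), bi(y))), x + y)
    expect_equal(bi_to_num(bi_mul(bi(x), bi(y %% 1e3))), x * (y %% 1e3))
    expect_equal(bi_cmp(bi(x), bi(y)), sign(x - y))
    if (x >= y) expect_equal(bi_to_num(bi_sub(bi(x), bi(y))), x - y)
  }
  expect_equal(bi_to_num(bi(0)), 0)
  expect_equal(bi_to_char(bi(0)), "0")
  expect_equal(bi_to_char(bi(1e15 + 7)), "1000000000000007")
})

test_that("carry propagation is correct across limb boundaries", {
  expect_equal(bi_to_num(bi_add(bi(999999), bi(1))), 1e6)
  expect_equal(bi_to_num(bi_mul(bi(999999), bi(999999))), 999999^2)
  expect_equal(bi_to_char(bi_sub(bi(1e6), bi(1))), "999999")
})

test_that("algebraic identities hold beyond double precision", {
  set.seed(2)
  a <- bi(floor(stats::runif(1, 1e14, 9e14)))
  b <- bi(floor(stats::runif(1, 1e14, 9e14)))
  c <- bi(floor(stats::runif(1, 1e14, 9e14)))
  # (a*b)*c == a*(b*c), a 45-digit product
  expect_equal(bi_cmp(bi_mul(bi_mul(a, b), c), bi_mul(a, bi_mul(b, c))), 0L)
  # distributivity: a*(b+c) == a*b + a*c
  expect_equal(bi_cmp(bi_mul(a, bi_add(b, c)),
                      bi_add(bi_mul(a, b), bi_mul(a, c))), 0L)
  # a*b > a*(b-1)
  expect_equal(bi_cmp(bi_mul(a, b), bi_mul(a, bi_sub(b, bi(1)))), 1L)
})

test_that("exact decimal expansion of ratios", {
  expect_equal(bi_ratio_decimal(bi(1), bi(3), 9L), "0.333333333")
  expect_equal(bi_ratio_decimal(bi(1), bi(8), 9L), "0.125000000")
  expect_equal(bi_ratio_decimal(bi(3), bi(4), 6L), "0.750000")
  expect_equal(bi_ratio_decimal(bi(5), bi(5), 4L), "1.0000")
  expect_equal(bi_ratio_decimal(bi(0), bi(7), 4L), "0.0000")
})

test_that("exact_ratio coerces and formats", {
  r <- alignsafe:::exact_ratio(bi(1), bi(2))
  expect_equal(as.numeric(r), 0.5)
  expect_equal(format(r, digits = 6), "0.500000")
})
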