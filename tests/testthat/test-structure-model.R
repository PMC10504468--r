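test_that("dot-bracket parsing recovers nested and layered pairs", {
  pt <- parse_dotbracket("((..))")
  expect_equal(pt$n, 6L)
  expect_equal(pair_keys(pt), c("1-6", "2-5"))
  expect_equal(pair_keys(parse_dotbracket("....")), character(0))
  # pseudoknot layers are matched independently
  pt2 <- parse_dotbracket("((..[[..))..]]")
  pr <- base_pairs(pt2)
  expect_equal(pair_keys(pt2), sort(c("1-10", "2-9", "5-14", "6-13")))
  expect_equal(pr$layer[pr$i %in% c(1, 2)], c(0L, 0L))
  expect_equal(pr$layer[pr$i %in% c(5, 6)], c(1L, 1L))
})

test_that("malformed structures fail with the offending position", {
  expect_error(parse_dotbracket("((.)"), "unmatched '\\(' at position 1")
  expect_error(parse_dotbracket(".))"), "unmatched '\\)' at position 2")
  expect_error(parse_dotbracket("..a."), "unknown character 'a' at position 3")
  expect_error(parse_dotbracket("(..]"), "unmatched")
  expect_error(parse_dotbracket(""), "empty")
})

test_that("the stack matcher agrees with a recursive-descent oracle", {
  set.seed(11)
  for (rep in 1:60) {
    s <- gen_balanced(sample(1:30, 1))
    pt <- parse_dotbracket(s)
    oracle <- rd_pairs(s)
    keys <- if (is.null(oracle)) character(0) else
      sort(sprintf("%d-%d", oracle[, 1], oracle[, 2]))
    expect_equal(pair_keys(pt), keys, info = s)
  }
})

test_that("parse then serialize round-trips, including bracket layers", {
  cases <- c("((..))", "....", "((..[[..))..]]", ".", "()",
             "((.((..))))", "<..{..}..>.[]")
  for (s in cases)
    expect_identical(serialize_dotbracket(parse_dotbracket(s)), s)
  set.seed(12)
  for (rep in 1:40) {
    s <- gen_balanced(sample(2:30, 1))
    expect_identical(serialize_dotbracket(parse_dotbracket(s)), s)
  }
})

test_that("imaginary centers are exact half-integer midpoints", {
  expect_identical(imaginary_center(25, 38), 31.5)
  expect_identical(imaginary_center(1, 2), 1.5)
  # a 1-nt bulge shifts the center by the minimal step of 0.5
  expect_equal(imaginary_center(3, 9) - imaginary_center(2, 9), 0.5)
  expect_error(imaginary_center(5, 5), "i < j")
  expect_error(imaginary_center(6, 2), "i < j")
})

test_that("helices are maximal stacked runs partitioning the pairs", {
  h <- helices(parse_dotbracket("((..))"))
  expect_length(h, 1L)
  expect_equal(nrow(h[[1]]$pairs), 2L)
  # a 1-nt bulge splits the stack in two
  h2 <- helices(parse_dotbracket("((.((..))))"))
  expect_length(h2, 2L)
  expect_equal(vapply(h2, function(x) nrow(x$pairs), 0L), c(2L, 2L))
  expect_length(helices(parse_dotbracket(".")), 0L)
  # every pair belongs to exactly one helix, and helices share one center
  set.seed(13)
  for (rep in 1:25) {
    pt <- parse_dotbracket(gen_balanced(sample(4:30, 1)))
    hh <- helices(pt)
    total <- sum(vapply(hh, function(x) nrow(x$pairs), 0L))
    expect_equal(total, nrow(base_pairs(pt)))
    for (x in hh) {
      expect_true(all(x$centers == x$centers[1]))
      if (nrow(x$pairs) > 1) {
        expect_equal(diff(x$pairs$i), rep(1L, nrow(x$pairs) - 1L))
        expect_equal(diff(x$pairs$j), rep(-1L, nrow(x$pairs) - 1L))
      }
    }
  }
})

test_that("pair tables are involutions with properly nested layers", {
  set.seed(14)
  for (rep in 1:20) {
    pt <- parse_dotbracket(gen_balanced(sample(2:30, 1)))
    paired <- which(!is.na(pt$partner))
    expect_true(all(pt$partner[pt$partner[paired]] == paired))
    expect_true(all(pt$partner[paired] != paired))
  }
})
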