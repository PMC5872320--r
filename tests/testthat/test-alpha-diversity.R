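test_that("Margalef richness matches the printed table and guards its domain", {
  expect_equal(roundHalfUp(margalef(11, 15), 2), 3.69)
  expect_equal(roundHalfUp(margalef(15, 27), 2), 4.25)
  expect_equal(margalef(1, 2), 0)
  expect_error(margalef(3, 1), "N >= 2")
  expect_error(margalef(5, 4), "exceed")
})

test_that("Brillouin uses log-gamma and is not scale invariant", {
  expect_equal(roundHalfUp(brillouin(c(2, 1)), 2), 0.37)
  expect_equal(brillouin(2), 0)
  expect_equal(roundHalfUp(brillouin(c(1, 1, 1)), 2), 0.60)
  # doubling all abundances changes Brillouin (0.60 -> 0.75) ...
  expect_equal(roundHalfUp(brillouin(c(2, 2, 2)), 2), 0.75)
  # ... but not the plug-in Simpson index
  expect_equal(simpsonDiversity(c(1, 1, 1)), simpsonDiversity(c(2, 2, 2)))
  # no overflow where factorials would explode
  expect_true(is.finite(brillouin(c(5000, 3000, 2000))))
  expect_error(brillouin(integer(0)), "empty")
})

test_that("Brillouin is bounded above by Shannon entropy", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample.int(40, sample(2:10, 1), replace = TRUE)
    p <- n / sum(n)
    expect_lte(brillouin(n), -sum(p * log(p)) + 1e-12)
  }
})

test_that("Simpson estimators match their definitions", {
  expect_equal(simpsonDiversity(c(1, 1)), 0.5)
  expect_equal(roundHalfUp(simpsonDiversity(c(2, 1)), 2), 0.44)
  expect_equal(simpsonDiversity(c(1, 1), "unbiased"), 1)
  expect_equal(simpsonDiversity(c(2, 1), "unbiased"), 1 - 2 / 6)
  # plug-in form is bounded by 1 - 1/S
  set.seed(7)
  for (i in 1:25) {
    n <- sample.int(30, sample(2:8, 1), replace = TRUE)
    expect_lte(simpsonDiversity(n), 1 - 1 / length(n) + 1e-12)
  }
  expect_error(simpsonDiversity(1, "unbiased"), "N >= 2")
})

test_that("Fisher's alpha solves the log-series relation", {
  expect_equal(roundHalfUp(as.numeric(fisherAlpha(11, 15)), 2), 18.60)
  expect_equal(roundHalfUp(as.numeric(fisherAlpha(15, 27)), 2), 13.90)
  expect_equal(roundHalfUp(as.numeric(fisherAlpha(5, 10)), 2), 3.98)
  expect_equal(roundHalfUp(as.numeric(fisherAlpha(4, 5)), 2), 9.28)
  expect_equal(roundHalfUp(as.numeric(fisherAlpha(1, 2)), 2), 0.80)
  # S = N: the root diverges, sentinel 0 with the degenerate flag
  fa <- fisherAlpha(5, 5)
  expect_identical(as.numeric(fa), 0)
  expect_true(attr(fa, "degenerate"))
  expect_error(fisherAlpha(6, 5), "exceed")
})

test_that("fisherAlpha residuals meet tolerance and the root is monotone in S", {
  for (N in c(10, 50, 200, 1000)) {
    prev <- 0
    for (S in unique(pmin(N - 1, c(1, 2, N %/% 2, N - 1)))) {
      a <- as.numeric(fisherAlpha(S, N))
      expect_lt(abs(a * log1p(N / a) - S), 1e-9)
      expect_gt(a, prev)   # strictly increasing in S at fixed N
      prev <- a
    }
  }
  # margalef shares the monotonicity in S
  expect_true(all(diff(margalef(1:20, 25)) > 0))
})

test_that("fisherAlpha agrees with vegan's independent estimator", {
  skip_if_not_installed("vegan")
  set.seed(3)
  for (i in 1:10) {
    n <- sample.int(25, sample(3:12, 1), replace = TRUE)
    if (length(n) >= sum(n)) next
    expect_equal(as.numeric(fisherAlpha(length(n), sum(n))),
                 as.numeric(vegan::fisher.alpha(n)), tolerance = 1e-6)
  }
})

test_that("diversityProfile reproduces the printed table on forced rows", {
  t7 <- loadFixture("table7")
  forced <- Filter(Negate(is.null), t7$forced_abundances)
  prof <- diversityProfile(forced, round = TRUE)
  printed <- t7$printed[match(prof$sample_id, t7$printed$sample_id), ]
  expect_equal(prof$simpson_1d, printed$simpson_1d)
  expect_equal(prof$brillouin, printed$brillouin)
  expect_equal(prof$margalef, printed$margalef)
  expect_equal(prof$fisher_alpha, printed$fisher_alpha)
  expect_identical(prof$degenerate_fisher, printed$taxa == printed$strains)
})

test_that("diversityProfile skips empty samples with a warning", {
  m <- matrix(c(2L, 1L, 0L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("S1", "S2")))
  oe <- OccurrenceExperiment(m, c(S1 = 8L, S2 = 8L))
  expect_warning(prof <- diversityProfile(oe), "S2")
  expect_identical(prof$sample_id, "S1")
  expect_identical(prof$S, 2L)
  expect_identical(prof$N, 3L)
})
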