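test_that("log-series community sampling is reproducible and in range", {
  set.seed(5); a <- sampleLogseriesCommunity(10, 500)
  set.seed(5); b <- sampleLogseriesCommunity(10, 500)
  expect_identical(a, b)
  expect_true(all(a >= 1))
  set.seed(5); s <- sampleLogseriesCommunity(10, 500, method = "sequential")
  expect_gte(sum(s), 500)
  expect_error(sampleLogseriesCommunity(-1, 10))
})

test_that("vanishing alpha concentrates the community on few species", {
  set.seed(6)
  S_tiny <- replicate(50, length(sampleLogseriesCommunity(1e-4, 100,
                                                          method = "sequential")))
  S_big <- replicate(50, length(sampleLogseriesCommunity(10, 100,
                                                         method = "sequential")))
  # one-species communities dominate in the limit and richness collapses
  expect_identical(as.integer(which.max(table(S_tiny))), 1L)
  expect_gt(mean(S_tiny == 1), 0.5)
  expect_lt(mean(S_tiny), mean(S_big) / 3)
})

test_that("surveys are bitwise reproducible under a fixed seed", {
  s1 <- generateSurvey(surveyParams(n_plants = 4, seed = 33))
  s2 <- generateSurvey(surveyParams(n_plants = 4, seed = 33))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$frame_totals, s2$frame_totals)
})

test_that("generated surveys satisfy every occurrence invariant", {
  for (seed in c(2, 19, 77)) {
    sv <- generateSurvey(surveyParams(seed = seed))
    expect_silent(validateIsolationRecords(sv$records))
    # dedup by construction
    key <- do.call(paste, sv$records[c("plant_id", "medium", "stem_age",
                                       "fragment_id", "species")])
    expect_false(anyDuplicated(key) > 0)
    oe <- buildOccurrenceMatrix(sv$records, "plant_id", sv$frame_totals)
    expect_true(validObject(oe))
    cr <- colonizationRate(oe)
    expect_true(all(cr$cr_percent >= 0 & cr$cr_percent <= 100))
  }
})

test_that("full host specificity makes plant communities disjoint", {
  sv <- generateSurvey(surveyParams(host_specificity = 1, seed = 8))
  oe <- buildOccurrenceMatrix(sv$records, "plant_id", sv$frame_totals)
  keep <- colSums(occurrenceCounts(oe)) > 0
  m <- similarityValues(similarityMatrix(oe[, keep]))
  expect_true(all(m[upper.tri(m)] == 0))
})

test_that("no colonization means no records and zero CR everywhere", {
  sv <- generateSurvey(surveyParams(colonization_prob = 0, seed = 4))
  expect_identical(nrow(sv$records), 0L)
  oe <- buildOccurrenceMatrix(sv$records, "plant_id", sv$frame_totals)
  expect_true(all(colonizationRate(oe)$cr_percent == 0))
})

test_that("community overlap declines as host specificity rises", {
  hs <- seq(0, 1, by = 0.25)
  mean_sim <- sapply(hs, function(h) {
    mean(sapply(1:5, function(seed) {
      sv <- generateSurvey(surveyParams(host_specificity = h, seed = seed,
                                        colonization_prob = 0.6))
      oe <- buildOccurrenceMatrix(sv$records, "plant_id", sv$frame_totals)
      keep <- colSums(occurrenceCounts(oe)) > 0
      v <- similarityValues(similarityMatrix(oe[, keep]))
      mean(v[upper.tri(v)])
    }))
  })
  expect_lt(cor(hs, mean_sim, method = "spearman"), 0)
  expect_lt(mean_sim[length(hs)], mean_sim[1])
})

test_that("the case-study scenario hits its calibrated summaries", {
  frac <- sapply(1:100, function(s)
    singleMediumFraction(scenarioPaperLike(seed = s)$records))
  expect_gte(mean(frac), 0.5)
  expect_lte(mean(frac), 0.7)
  sv <- scenarioPaperLike(seed = 1)
  expect_identical(unname(sv$frame_totals[1]), 24L)
  oe <- buildOccurrenceMatrix(sv$records, "plant_id", sv$frame_totals)
  cr <- colonizationRate(oe)
  expect_true(all(cr$cr_percent >= 0 & cr$cr_percent <= 100))
  expect_gt(max(cr$cr_percent), 0)   # non-degenerate for the default seed
})
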