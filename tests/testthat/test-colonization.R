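test_that("colonization rate matches the printed survey examples", {
  t5 <- loadFixture("table5")
  oe <- buildOccurrenceMatrix(t5$records, "plant_id", t5$frame_totals)
  cr <- colonizationRate(oe)
  get <- function(p) roundHalfUp(cr$cr_percent[cr$sample_id == p], 2)
  expect_equal(get("TF1"), 37.5)  # flagged plant: records support only 3 of 8
  expect_equal(get("TF5"), 62.50) # 5 of 8
  expect_equal(get("LP2"), 92.11) # 35 of 38
  expect_equal(get("LP4"), 55.00) # 11 of 20
})

test_that("zero colonization and undefined denominators behave", {
  oe <- buildOccurrenceMatrix(make_records("P1", "f1", "sp1"),
                              "plant_id", c(P1 = 4L, P2 = 20L))
  cr <- colonizationRate(oe, "P2")
  expect_equal(cr$cr_percent, 0)
  expect_error(colonizationRate(oe, "nope"), "unknown sample")
  # CR needs fragment-level provenance
  hand <- OccurrenceExperiment(matrix(1L, 1, 1,
                                      dimnames = list("sp1", "A")),
                               c(A = 8L))
  expect_error(colonizationRate(hand), "fragment-level")
})

test_that("CR is invariant to a second species on a colonized fragment", {
  base <- make_records("P1", c("f1", "f2"), "sp1")
  extra <- rbind(base, make_records("P1", "f1", "sp2"))
  tot <- c(P1 = 8L)
  cr1 <- colonizationRate(buildOccurrenceMatrix(base, "plant_id", tot))
  cr2 <- colonizationRate(buildOccurrenceMatrix(extra, "plant_id", tot))
  expect_equal(cr1$cr_percent, cr2$cr_percent)
})

test_that("colonization frequency reproduces printed cells and aggregates", {
  t5 <- loadFixture("table5")
  oe <- buildOccurrenceMatrix(t5$records, "plant_id", t5$frame_totals)
  cf <- colonizationFrequency(oe, "per_sample")
  cell <- function(p, s)
    roundHalfUp(cf$cf_percent[cf$sample_id == p & cf$species == s], 2)
  expect_equal(cell("LP4", "Preussia sp. 1"), 25.00)
  expect_equal(cell("LP2", "Neofusicoccum sp. 3"), 34.21)  # 13/38
  # overall counts are the sum of per-sample counts
  ov <- colonizationFrequency(oe, "overall")
  per <- tapply(cf$count, cf$species, sum)
  expect_identical(as.integer(per[ov$species]), as.integer(ov$count))
  expect_true(all(ov$denominator == sum(totalFragments(oe))))
  # dense output reports explicit zeros
  dense <- colonizationFrequency(oe, "per_sample", dense = TRUE)
  expect_identical(nrow(dense), nrow(oe) * ncol(oe))
  expect_true(any(dense$cf_percent == 0))
})

test_that("CR summaries use the arithmetic mean and the n-1 SD", {
  t4 <- loadFixture("table4")
  s <- summarizeCR(t4$printed$cr_percent)
  expect_equal(roundHalfUp(s$mean, 2), 50.79)  # printed AVG row is 50.78
  expect_equal(s$sd, sd(t4$printed$cr_percent))
  expect_equal(summarizeCR(c(0, 100))$mean, 50)
  expect_true(is.na(summarizeCR(42)$sd))
  expect_error(summarizeCR(numeric(0)), "empty")
})
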