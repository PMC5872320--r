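test_that("fixture shapes match the published tables", {
  t7 <- loadFixture("table7")
  expect_identical(nrow(t7$printed), 9L)
  expect_named(t7$printed, c("sample_id", "taxa", "strains", "simpson_1d",
                             "brillouin", "margalef", "fisher_alpha"))
  expect_identical(nrow(loadFixture("table5")$printed), 50L)
  expect_identical(nrow(loadFixture("table6")$printed), 34L)
  expect_identical(nrow(loadFixture("table4")$printed), 10L)
  expect_identical(nrow(loadFixture("table8")$printed), 5L)
  t10 <- loadFixture("table10")
  expect_identical(nrow(t10$printed), 10L)  # 5 communities, upper triangle
  expect_error(loadFixture("table99"))
})

test_that("forced abundance vectors are consistent with their (S, N)", {
  t7 <- loadFixture("table7")
  for (s in names(t7$forced_abundances)) {
    v <- t7$forced_abundances[[s]]
    if (is.null(v)) next
    row <- t7$printed[t7$printed$sample_id == s, ]
    expect_identical(length(v), as.integer(row$taxa))
    expect_identical(sum(v), as.integer(row$strains))
  }
  # under-determined rows are left unforced
  expect_null(t7$forced_abundances$`LP1/EG`)
})

test_that("reconstructed records round-trip the printed CF cells", {
  t5 <- loadFixture("table5")
  oe <- buildOccurrenceMatrix(t5$records, "plant_id", t5$frame_totals)
  cf <- colonizationFrequency(oe, "per_sample")
  p <- t5$printed
  for (i in which(t5$reconstructable)) {
    hit <- cf$sample_id == p$plant_id[i] & cf$species == p$species[i]
    expect_equal(roundHalfUp(cf$cf_percent[hit], 2), p$cf_percent[i],
                 info = paste(p$plant_id[i], p$species[i]))
  }
  # the known non-reconstructable rows are flagged, not silently included
  flagged <- p[!t5$reconstructable, ]
  expect_setequal(unique(paste(flagged$plant_id, flagged$species)),
                  c("TF1 Thielavia sp. 1", "LP1 Aspergillus flavus"))
  expect_identical(names(which(!t5$cr_reconstructable)), "TF1")
})

test_that("case-study presence sets are normalized and plausible", {
  t9 <- loadFixture("table9")
  expect_named(t9$medium_sets, c("PDA", "LCA", "V8"))
  # orthographic variant folded into the accepted species name
  expect_false(any(grepl("austral$", unlist(t9$medium_sets))))
  all_sp <- unique(unlist(t9$medium_sets))
  single <- sum(table(unlist(lapply(t9$medium_sets, unique)))[all_sp] == 1)
  expect_identical(single, 14L)   # 14 species on one medium only
  expect_named(t9$age_sets, c("le_1yr", "gt_1yr"))
})
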