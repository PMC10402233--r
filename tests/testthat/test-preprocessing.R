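# Small synthetic descriptor tables used across the preprocessing tests.
makeShapeRows <- function(participant, electrode, amplitude, frequency,
                          area, n = 1, electrode2 = NA_character_) {
  data.frame(participant = participant, trial = seq_len(n),
             electrode1 = electrode, electrode2 = electrode2,
             amplitude = amplitude, frequency = frequency,
             n_phosphenes = 1, area = area, perimeter = sqrt(area) * 4,
             major = sqrt(area) * 1.5, minor = sqrt(area) * 0.8)
}

test_that("standard-pulse normalization divides by the participant reference", {
  df <- rbind(
    makeShapeRows("P1", "A1", 2, 20, area = 100),
    makeShapeRows("P1", "B2", 2, 20, area = 300),
    makeShapeRows("P1", "A1", 4, 20, area = 400),
    makeShapeRows("P2", "A1", 2, 20, area = 50))
  out <- normalizeDescriptors(df)
  # P1 standard mean area = 200: the 400 record maps to 2.0
  expect_equal(out$area[3], 2)
  expect_equal(out$area[1:2], c(0.5, 1.5))
  expect_equal(out$area[4], 1)  # P2's only standard record equals its mean
  # per-participant mean of normalized standard-pulse values is exactly 1
  std <- out$amplitude == 2 & out$frequency == 20
  for (p in c("P1", "P2"))
    expect_equal(mean(out$area[std & out$participant == p]), 1)
  dfBad <- makeShapeRows("P3", "A1", 4, 20, area = 10)
  expect_error(normalizeDescriptors(rbind(df, dfBad)), "P3")
})

test_that("trial averaging collapses repeated stimuli and keeps counts", {
  five <- makeShapeRows("P1", "A1", 2, 20, area = 100, n = 5)
  agg <- averageTrials(five)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$area, 100)
  expect_equal(agg$n_trials, 5)
  tri <- makeShapeRows("P1", "A1", 2, 20, area = 1, n = 3)
  tri$area <- c(1, 2, 3)
  expect_equal(averageTrials(tri)$area, 2)
  # 12 drawings over 3 keys with counts {5, 4, 3}
  df <- rbind(makeShapeRows("P1", "A1", 2, 20, 10, n = 5),
              makeShapeRows("P1", "A2", 2, 20, 20, n = 4),
              makeShapeRows("P2", "A1", 4, 20, 30, n = 3))
  agg <- averageTrials(df)
  expect_equal(nrow(agg), 3)
  expect_equal(sort(agg$n_trials), c(3, 4, 5))
  # paired keys (electrode2) survive the aggregation
  pr <- makeShapeRows("P1", "A1", 2, 20, 10, n = 2, electrode2 = "B2")
  agg2 <- averageTrials(rbind(df, pr))
  expect_equal(nrow(agg2), 4)
  expect_equal(sum(!is.na(agg2$electrode2)), 1)
})

test_that("normalization and averaging commute for shared-key trials", {
  df <- makeShapeRows("P1", "A1", 2, 20, area = 1, n = 6)
  df$area <- c(80, 90, 100, 110, 120, 100)
  a1 <- averageTrials(normalizeDescriptors(df))
  n2 <- normalizeDescriptors(averageTrials(df))
  expect_equal(a1$area, n2$area)
})

test_that("outlier screening applies the 2.5-SD population rule per group", {
  df <- makeShapeRows("P1", "A1", 2, 20, area = 1, n = 5)
  df$area <- c(0, 0, 0, 0, 10)  # population z of 10 is 2.0: kept
  kept <- removeOutliers(df, cols = "area")
  expect_equal(nrow(kept), 5)
  expect_equal(abs(10 - mean(df$area)) / sqrt(mean((df$area - mean(df$area))^2)),
               2, tolerance = 1e-12)
  cst <- df; cst$area <- 7
  expect_equal(nrow(removeOutliers(cst, cols = "area")), 5)
  set.seed(9)
  big <- makeShapeRows("P1", "A1", 2, 20, area = 1, n = 400)
  big$area <- rnorm(400)
  big$area[17] <- mean(big$area[-17]) + 3.4 * sd(big$area[-17])
  out <- removeOutliers(big, cols = "area")
  expect_false(17 %in% as.integer(rownames(out)))
  expect_true(nrow(attr(out, "removed")) >= 1)
  expect_equal(attr(out, "removed")$flagged_by[1], "area")
})

test_that("power transforms use 1/3 for area and 1/2 elsewhere, monotonically", {
  expect_equal(powerTransform(8, "area"), 2)
  expect_equal(powerTransform(9, "perimeter"), 3)
  expect_equal(powerTransform(0, "area"), 0)
  expect_error(powerTransform(-1, "area"), "non-negative")
  set.seed(10)
  v <- sort(runif(50, 0, 500))
  for (k in c("area", "perimeter", "major", "minor"))
    expect_true(all(diff(powerTransform(v, k)) >= 0))
})

test_that("z-scoring uses the population SD", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1) * 1.224744871391589)
  expect_error(zscore(rep(4, 5)), "constant")
})

test_that("the design table joins predictors and standardizes them", {
  shapes <- rbind(
    makeShapeRows("P1", "A1", 2, 20, 1.0), makeShapeRows("P1", "A2", 2, 20, 1.5),
    makeShapeRows("P1", "A1", 4, 20, 2.0), makeShapeRows("P1", "A2", 4, 20, 2.5),
    makeShapeRows("P1", "A1", 2, 20, 2.2, electrode2 = "A2"))
  eTab <- data.frame(participant = "P1", electrode = c("A1", "A2"),
                     efd_um = c(1000, 2000), erd_um = c(100, 140))
  pTab <- data.frame(participant = "P1", electrode1 = "A1",
                     electrode2 = "A2", between_axon_um = 300,
                     along_axon_um = 500)
  des <- assembleDesignTable(shapes, eTab, pTab)
  expect_equal(des$type, c(rep("single", 4), "paired"))
  # paired EFD is the mean of the two electrodes'
  expect_equal(des$efd_um[5], 1500)
  # z-scored predictors have population mean 0 / SD 1
  expect_equal(mean(des$amplitude_z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(des$amplitude_z^2)), 1, tolerance = 1e-12)
  # sum-of-singles picks the matching stimulus rows
  expect_equal(des$sum_area[5], 1.0 + 1.5)
  expect_true(is.na(des$sum_area[1]))
  # unmatched electrode keys are reported
  expect_error(assembleDesignTable(shapes, eTab[1, , drop = FALSE], pTab),
               "A2")
  shapes2 <- shapes; shapes2$electrode2[5] <- "B9"
  expect_error(assembleDesignTable(shapes2, eTab, pTab), "B9")
})

test_that("constant predictors are dropped rather than z-scored", {
  shapes <- rbind(makeShapeRows("P1", "A1", 2, 20, 1),
                  makeShapeRows("P1", "A2", 2, 20, 2),
                  makeShapeRows("P1", "A3", 4, 20, 3))
  eTab <- data.frame(participant = "P1", electrode = c("A1", "A2", "A3"),
                     efd_um = c(1000, 1500, 2000), erd_um = 0)
  des <- assembleDesignTable(shapes, eTab)
  expect_false("erd_z" %in% colnames(des))  # zero everywhere, like an
  expect_true("efd_z" %in% colnames(des))   # apposed-array participant
})

test_that("the full preprocessing pipeline is deterministic", {
  set.seed(123)
  cfg <- testConfig()
  dat <- sampleDataset(cfg, seed = 3, nElectrodes = 2, nPairs = 2)
  st <- shapeTable(dat$drawings)
  d1 <- prepareDesign(st, dat$electrodeTable, dat$pairTable)
  d2 <- prepareDesign(st, dat$electrodeTable, dat$pairTable)
  expect_identical(d1, d2)
  # single-electrode outliers screened; paired rows never removed
  rem <- attr(d1, "removed")
  if (nrow(rem)) expect_true(all(is.na(rem$electrode2)))
  # standard-pulse normalization sanity on the synthetic set
  norm <- normalizeDescriptors(st)
  std <- norm$amplitude == 2 & norm$frequency == 20 & is.na(norm$electrode2)
  for (p in unique(norm$participant))
    expect_equal(mean(norm$area[std & norm$participant == p]), 1)
})
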