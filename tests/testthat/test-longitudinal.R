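test_that("percent-of-baseline reproduces the published trajectories", {
  tab <- snpStudyMorphometry()
  nfd <- "nerve_fibre_density_mm_per_mm2"
  snf <- "single_nerve_fibres"
  expected <- list(
    c("applicator", nfd, 5, 26, 31, 85),
    c("central",    nfd, 4, 37, 33, 71),
    c("distal",     nfd, 27, 54, 73, 91),
    c("applicator", snf, 2, 16, 17, 78),
    c("central",    snf, 3, 22, 41, 50),
    c("distal",     snf, 29, 78, 108, 117))
  for (e in expected) {
    p <- percentOfBaseline(tab, e[2], e[1])
    expect_equal(p$percent, c(100L, as.integer(e[3:6])),
                 info = paste(e[1], e[2]))
  }
})

test_that("percent-of-baseline is scale invariant and validates its input", {
  tab <- data.frame(metric = "m", zone = "distal",
                    timepoint = timePoints(),
                    value = c(40, 10, 20, 30, 44))
  p1 <- percentOfBaseline(tab, "m", "distal")
  tab2 <- tab; tab2$value <- tab2$value * 3.7
  expect_identical(p1$percent, percentOfBaseline(tab2, "m", "distal")$percent)
  expect_equal(p1$percent[1], 100L)

  const <- tab; const$value <- 7
  expect_true(all(percentOfBaseline(const, "m", "distal")$percent == 100L))

  nob <- tab[tab$timepoint != "baseline", ]
  expect_error(percentOfBaseline(nob, "m", "distal"), "baseline")
  zerob <- tab; zerob$value[1] <- 0
  expect_error(percentOfBaseline(zerob, "m", "distal"), "baseline")
  expect_error(percentOfBaseline(tab, "m", "limbal"), "zone")
})

test_that("replicate aggregation uses mean and sample SD", {
  doses <- c(278, 293, 550, 520, 527, 387, 1070, 500, 573)
  a <- aggregateReplicates(doses)
  expect_equal(a$mean, 522)
  expect_equal(roundHalfAway(a$sd), 233)
  expect_equal(replicateQuantile(doses), 520)
  expect_equal(aggregateReplicates(c(5, 5)), list(mean = 5, sd = 0, n = 2L))
  expect_equal(aggregateReplicates(4)$sd, 0)
  expect_error(aggregateReplicates(numeric(0)), "value")
})

test_that("sensation percentages and the normal band match the protocol", {
  expect_equal(sensationPercent(54, 58), 93L)
  expect_equal(sensationPercent(23, 58), 40L)
  expect_equal(sensationPercent(60, 60), 100L)
  expect_equal(sensationPercent(39, 58), 67L)
  # 56/58 = 96.55 rounds to 97 under half-away rounding
  expect_equal(sensationPercent(56, 58), 97L)
  expect_error(sensationPercent(54, 0), "baseline")
  expect_error(sensationPercent(65, 58), "filament")
  expect_identical(isNormalSensation(c(45, 50, 60, 20)),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("the bulk percent table covers every series and skips broken ones", {
  tab <- rbind(snpStudyMorphometry(), snpStudySensation())
  out <- percentOfBaselineTable(tab)
  expect_equal(nrow(out), 9 * 3 * 5)   # 8 morphometry metrics + sensation
  snfc <- out[out$metric == "single_nerve_fibres" &
              out$zone == "central", "percent"]
  expect_equal(snfc, c(100L, 3L, 22L, 41L, 50L))

  broken <- rbind(tab, data.frame(metric = "extra", zone = "distal",
                                  timepoint = "month1", value = 5, sd = 0))
  expect_warning(out2 <- percentOfBaselineTable(broken), "skipping")
  expect_equal(nrow(out2), nrow(out))
})
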