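test_that("conservation summaries use sample sd and strict thresholds", {
  s <- conservationSummary(c(90, 90))
  expect_equal(s$mean, 90)
  expect_equal(s$sd, 0)
  expect_error(conservationSummary(93.7), "at least 2")
  fx <- loadFixture("gsis69")
  r <- records(fx)
  cox <- r[r$abbrev %in% c("Cox1", "Cox2"), ]
  expect_equal(conservationSummary(cox)$mean, 91.15)
})

test_that("subset means always lie within the subset range", {
  fx <- loadFixture("gsis69")
  v <- records(fx)$hm_similarity
  set.seed(5)
  for (k in 1:20) {
    sub <- sample(v, sample(2:30, 1))
    s <- conservationSummary(sub)
    expect_gte(s$mean, s$min)
    expect_lte(s$mean, s$max)
  }
})

test_that("quintile bins split ranks evenly with ties going low", {
  b <- quintileBins(setNames(1:10, paste0("p", 1:10)))
  expect_equal(unname(b[c("p1", "p2")]), c(1L, 1L))
  expect_equal(unname(b[c("p9", "p10")]), c(5L, 5L))
  expect_equal(as.vector(table(b)), rep(2L, 5))
  allEq <- quintileBins(rep(50, 8))
  expect_equal(unique(allEq), 1L)     # ties share one bin
  expect_error(quintileBins(1:4), "at least 5")
  set.seed(9)
  v <- sample(1000, 69)               # distinct values
  expect_lte(diff(range(table(quintileBins(v)))), 1)
})

test_that("the study cohort's extremes land in the outer quintiles", {
  fx <- loadFixture("gsis69")
  b <- quintileBins(fx)
  expect_equal(unname(b["SOD2e"]), 1L)
  expect_equal(unname(b["FBb"]), 5L)
})

test_that("Tukey fences flag the planted low outlier", {
  r <- makeRecords(c(90, 91, 92, 93, 60))
  g <- setNames(rep("G", 5), r$abbrev)
  out <- pathwayOutliers(r, g)
  expect_equal(out$protein, "p05")
  expect_equal(out$side, "low")
  fo <- fenceOracle(c(90, 91, 92, 93, 60))
  expect_equal(unname(attr(out, "fences")$G), unname(fo))
})

test_that("identical values and tiny groups yield no outliers", {
  r <- makeRecords(rep(95, 6))
  expect_equal(nrow(pathwayOutliers(r, setNames(rep("G", 6), r$abbrev))), 0L)
  r2 <- makeRecords(c(90, 50, 95))
  expect_warning(out <- pathwayOutliers(r2,
                                        setNames(rep("G", 3), r2$abbrev)),
                 "fewer than 4")
  expect_equal(nrow(out), 0L)
  expect_error(pathwayOutliers(r2, setNames(character(0), character(0))),
               "empty grouping")
})

test_that("the cohort's four rapidly evolving adapters are low outliers", {
  fx <- loadFixture("gsis69")
  out <- suppressWarnings(
    pathwayOutliers(fx, assignAnovaGroups(fx, "five_group_figure3")))
  low <- out$protein[out$side == "low"]
  expect_true(all(c("SOD2e", "IDHcp", "PDCc", "NDK") %in% low))
  expect_equal(out$group[out$protein == "SOD2e"], "S")
  expect_true(all(out$group[out$protein %in%
                              c("IDHcp", "PDCc", "NDK")] == "TPN"))
  ## fences agree with the longhand quartile computation per group
  r <- records(fx)
  grp <- assignAnovaGroups(fx, "five_group_figure3")
  for (g in c("G", "R", "S", "TPN")) {
    v <- r$hm_similarity[grp[r$abbrev] == g]
    expect_equal(unname(attr(out, "fences")[[g]]), unname(fenceOracle(v)))
  }
})
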