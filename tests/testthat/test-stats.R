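test_that("grouping schemes assign multi-pathway proteins by first code", {
  fx <- loadFixture("gsis69")
  g6 <- assignAnovaGroups(fx, "six_group")
  g5 <- assignAnovaGroups(fx, "five_group_figure3")
  expect_equal(unname(g6["CS"]), "T")     # "T,P" -> first listed
  expect_equal(unname(g6["OGC"]), "PN")   # "N,P" -> shuttle/pyruvate merge
  expect_equal(unname(g5["OGC"]), "TPN")
  expect_equal(unname(g6["GK"]), "G")
  expect_equal(unname(g5["GK"]), "G")
  expect_setequal(unique(g6), c("G", "T", "PN", "M", "R", "S"))
  expect_setequal(unique(g5), c("G", "M", "R", "S", "TPN"))
  bad <- makeRecords(c(90, 91))
  bad$pathways[1] <- ""
  expect_error(assignAnovaGroups(bad), "empty pathway")
})

test_that("one-way ANOVA rejects degenerate designs", {
  r <- makeRecords(c(90, 90, 90, 90), pathways = c("G", "G", "T", "T"))
  expect_error(divergenceAnova(r), "F undefined")
  one <- makeRecords(c(90, 91, 92))
  expect_error(divergenceAnova(one), "at least 2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(61)
  for (k in 1:10) {
    r <- makeRecords(c(rnorm(8, 90, 2), rnorm(6, 93, 2)),
                     pathways = c(rep("G", 8), rep("R", 6)))
    an <- divergenceAnova(r)
    tt <- t.test(hm_similarity ~ pathways, data = r, var.equal = TRUE)
    expect_equal(an$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an$df_between, 1L)
  }
})

test_that("Tukey HSD separates a strongly shifted group and only that group", {
  set.seed(67)
  r <- makeRecords(c(rnorm(10, 90, 1), rnorm(10, 90, 1), rnorm(10, 80, 1)),
                   pathways = rep(c("G", "T", "R"), each = 10))
  tk <- tukeyHsd(r)
  hitR <- tk[tk$group_a == "R" | tk$group_b == "R", ]
  expect_true(all(hitR$p_adj < 0.05))
  other <- tk[tk$group_a != "R" & tk$group_b != "R", ]
  expect_true(all(other$p_adj > 0.05))
  expect_equal(nrow(tk), choose(3, 2))
  ## adjusted p exceeds the unadjusted pairwise p for every pair
  for (i in seq_len(nrow(tk))) {
    a <- r$hm_similarity[r$pathways == tk$group_a[i]]
    b <- r$hm_similarity[r$pathways == tk$group_b[i]]
    expect_gte(tk$p_adj[i], t.test(a, b, var.equal = TRUE)$p.value - 1e-12)
  }
  same <- makeRecords(c(rnorm(10, 90, 1)), pathways = rep("G", 10))
  same2 <- rbind(same, transform(same, abbrev = paste0(abbrev, "b"),
                                 pathways = "T"))
  expect_gt(tukeyHsd(same2)$p_adj, 0.9)
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  expect_equal(spearmanCorrelation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCorrelation(1:10, -(1:10))$rho, -1)
  set.seed(71)
  x <- rnorm(10)
  y <- rnorm(10)
  sc <- spearmanCorrelation(x, y)
  expect_equal(sc$rho, cor(rank(x), rank(y)))
  ## invariant under strictly monotone transforms
  expect_equal(spearmanCorrelation(exp(x), y)$rho, sc$rho)
  expect_equal(spearmanCorrelation(x, y^3 + 5 * y)$rho, sc$rho)
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCorrelation(1:2, 2:1), "at least 3")
})

test_that("small-sample Spearman p comes from exact enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  sc <- spearmanCorrelation(x, y)
  ## exact two-sided tail: enumerate all 120 permutations longhand
  rhoOf <- function(p) cor(x, y[p])
  perms <- do.call(rbind, combinat_perms <- lapply(
    asplit(as.matrix(expand.grid(rep(list(1:5), 5))), 1),
    function(p) if (all(sort(p) == 1:5)) p))
  rhos <- apply(perms, 1, rhoOf)
  pExact <- mean(abs(rhos) >= abs(sc$rho) - 1e-12)
  expect_equal(sc$p_two_tailed, pExact, tolerance = 1e-10)
})

test_that("disease comparisons cover similarity, age class and selection", {
  ## identical arms: t statistic 0, p = 1
  r <- makeRecords(c(90, 95, 90, 95), disease = c(TRUE, TRUE, FALSE, FALSE))
  dc <- diseaseComparisons(r)
  expect_equal(dc$t_p, 1)
  expect_equal(dc$mean_disease, dc$mean_other)
  expect_error(diseaseComparisons(makeRecords(c(90, 91, 92),
                                              disease = c(TRUE, FALSE,
                                                          FALSE))),
               "at least 2")
  fx <- loadFixture("gsis69")
  full <- diseaseComparisons(fx)
  expect_equal(full$n_disease, 24L)
  expect_equal(full$n_disease_universal, 20L)
  expect_equal(sum(full$possel_table), 69)
  expect_equal(unname(full$possel_table["TRUE", "TRUE"]), 1)  # ETF-QO only
})
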