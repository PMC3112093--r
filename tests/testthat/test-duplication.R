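test_that("duplication vectors count flagged nodes on the focal lineage", {
  gt <- readGeneTree("((focal,x)[&&NHX:D=Y:T=Euteleostomi:A=420],y);")
  v <- dupCounts(extractDuplicationVector(gt, "focal"))[1, ]
  expect_equal(unname(v["Euteleostomi"]), 1L)
  expect_equal(sum(v), 1L)
  ## duplication on a branch not ancestral to the focal leaf contributes 0
  gt2 <- readGeneTree("((a,b)[&&NHX:D=Y:T=Theria:A=166],focal);")
  expect_equal(sum(dupCounts(extractDuplicationVector(gt2, "focal"))), 0L)
  expect_error(extractDuplicationVector(gt, "nope"), "not in tree")
})

test_that("family-founding markers truncate the vector and old taxa fall outside", {
  s <- paste0("(((focal,p1)[&&NHX:D=Y:T=Theria:A=166],p2)",
              "[&&NHX:D=Y:T=Euteleostomi:A=420:F=Y],out);")
  v <- dupCounts(extractDuplicationVector(readGeneTree(s), "focal"))[1, ]
  expect_equal(unname(v["Euteleostomi"]), 0L)  # founder itself excluded
  expect_equal(unname(v["Theria"]), 1L)
  ## pre-vertebrate duplication is excluded by the schedule window
  s2 <- "((focal,p)[&&NHX:D=Y:T=Bilateria:A=580],out);"
  expect_equal(sum(dupCounts(extractDuplicationVector(readGeneTree(s2),
                                                      "focal"))), 0L)
  ## unmappable taxon: strict errors, lenient warns and drops
  s3 <- "((focal,p)[&&NHX:D=Y:T=Wonderland:A=5],out);"
  expect_error(extractDuplicationVector(readGeneTree(s3), "focal"),
               "unmappable")
  expect_warning(
    v3 <- extractDuplicationVector(readGeneTree(s3), "focal",
                                   strict = FALSE), "unmappable")
  expect_equal(sum(dupCounts(v3)), 0L)
})

test_that("distances are Euclidean, symmetric and metric", {
  sched <- defaultTaxonSchedule()
  mk <- function(gene, counts) new("DuplicationHistory",
                                   counts = matrix(counts, 1,
                                                   dimnames = list(gene,
                                                                   sched$taxon)),
                                   schedule = sched)
  z <- rep(0L, 8)
  a <- z; a[1] <- 1L
  b <- z; b[2] <- 1L
  dh <- combineHistories(list(mk("g1", a), mk("g2", a), mk("g3", b)))
  dm <- euclideanDistanceMatrix(dh)
  expect_equal(dm["g1", "g2"], 0)
  expect_equal(dm["g1", "g3"], sqrt(2))
  expect_equal(dm, t(dm))
  set.seed(19)
  m <- matrix(rpois(40, 2), 5, 8,
              dimnames = list(paste0("g", 1:5), sched$taxon))
  dm2 <- euclideanDistanceMatrix(m)
  for (i in 1:5) for (j in 1:5)
    expect_equal(dm2[i, j], sqrt(sum((m[i, ] - m[j, ])^2)))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(dm2[i, j], dm2[i, k] + dm2[k, j] + 1e-12)
  badSched <- sched[1:4, ]
  mk2 <- new("DuplicationHistory",
             counts = matrix(0L, 1, 4, dimnames = list("g9",
                                                       badSched$taxon)),
             schedule = badSched)
  expect_error(combineHistories(list(mk("g1", a), mk2)), "mixed")
})

test_that("zero-height clusters are exactly the equal-vector partition", {
  set.seed(3)
  for (linkage in c("complete", "average", "single")) {
    m <- matrix(rpois(12 * 4, 1), 12, 4)
    rownames(m) <- paste0("g", 1:12)
    cl <- hierarchicalCluster(euclideanDistanceMatrix(m), linkage)$clusters
    key <- apply(m, 1, paste, collapse = ",")
    expect_equal(length(unique(cl)), length(unique(key)))
    expect_true(all(tapply(key, cl, function(k) length(unique(k))) == 1))
  }
  expect_error(hierarchicalCluster(matrix(1:6, 2, 3)), "square")
})

test_that("identical-history genes among diverse ones test as clustered", {
  set.seed(41)
  sched <- defaultTaxonSchedule()
  m <- matrix(rpois(20 * 8, 1.5), 20, 8,
              dimnames = list(paste0("g", 1:20), sched$taxon))
  m[1:4, ] <- rep(c(2L, rep(0L, 7)), each = 4)  # four identical histories
  dm <- euclideanDistanceMatrix(m)
  memb <- setNames(c(rep("grp", 4), rep("bg", 16)), rownames(m))
  res <- groupClusteringTest(dm, memb, "grp", nGroupsTested = 3)
  expect_lt(res@pRaw, 0.01)
  expect_equal(res@direction, "clustered")
  expect_equal(res@nWithinPairs, 6L)
  expect_equal(res@nBackgroundPairs, choose(20, 2) - 6L)
  expect_equal(res@pBonferroni, min(1, res@pRaw * 3))
  expect_error(groupClusteringTest(dm, memb[1], "grp"), "fewer than 2")
})

test_that("private divergent histories in a homogeneous background anticluster", {
  sched <- defaultTaxonSchedule()
  m <- matrix(0L, 20, 8, dimnames = list(paste0("g", 1:20), sched$taxon))
  for (i in 1:4) m[i, i] <- 5L  # each member has its own private pattern
  dm <- euclideanDistanceMatrix(m)
  memb <- setNames(c(rep("grp", 4), rep("bg", 16)), rownames(m))
  res <- groupClusteringTest(dm, memb, "grp")
  expect_equal(res@direction, "anticlustered")
  expect_lt(res@pRaw, 0.05)
})

test_that("leave-one-out retesting isolates single-gene signals", {
  sched <- defaultTaxonSchedule()
  ## signal carried entirely by one outlier gene
  m <- matrix(0L, 20, 8, dimnames = list(paste0("g", 1:20), sched$taxon))
  m[1, ] <- 9L
  dm <- euclideanDistanceMatrix(m)
  memb <- setNames(c(rep("grp", 4), rep("bg", 16)), rownames(m))
  full <- groupClusteringTest(dm, memb, "grp")
  expect_equal(full@direction, "anticlustered")
  without <- excludeGeneAndRetest(dm, memb, "grp", "g1")
  expect_equal(without@direction, "none")
  expect_gt(without@pRaw, 0.05)
  ## distributed signal survives excluding any single member
  m2 <- matrix(0L, 20, 8, dimnames = list(paste0("g", 1:20), sched$taxon))
  for (i in 1:4) m2[i, i] <- 5L
  dm2 <- euclideanDistanceMatrix(m2)
  for (g in paste0("g", 1:4)) {
    res <- excludeGeneAndRetest(dm2, memb, "grp", g)
    expect_equal(res@direction, "anticlustered")
    expect_lt(res@pRaw, 0.05)
  }
  ## excluding a non-member leaves the result unchanged
  expect_warning(same <- excludeGeneAndRetest(dm2, memb, "grp", "g9"),
                 "not in group")
  ref <- groupClusteringTest(dm2, memb, "grp")
  expect_equal(same@pRaw, ref@pRaw)
  small <- setNames(c("grp", "grp", rep("bg", 18)), rownames(m2))
  expect_error(excludeGeneAndRetest(dm2, small, "grp", "g1"),
               "fewer than 2")
})

test_that("extracted vectors equal generator ground truth tree by tree", {
  set.seed(55)
  for (k in 1:50) {
    st <- synthGeneTree(dupRates = runif(8, 0, 2))
    got <- dupCounts(extractDuplicationVector(st$tree, "focal"))[1, ]
    expect_equal(got, st$truth)
  }
})
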