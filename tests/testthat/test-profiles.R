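test_that("the age classification rule follows the fixed order", {
  cnt <- function(p, e, m, v = 0)
    c(prokaryote = p, nonmetazoan_eukaryote = e,
      nonmammalian_metazoan = m, vertebrate = v)
  expect_equal(classifyProfile(cnt(6, 0, 0)), "U")
  expect_equal(classifyProfile(cnt(5, 1, 0)), "E")  # five does not qualify
  expect_equal(classifyProfile(cnt(5, 0, 0)), "V")
  expect_equal(classifyProfile(cnt(0, 0, 2)), "M")
  expect_equal(classifyProfile(cnt(0, 0, 0)), "V")
})

test_that("the rule partitions hit-count space exhaustively", {
  for (p in 0:10) for (e in 0:10) for (m in 0:10) {
    got <- classifyProfile(c(prokaryote = p, nonmetazoan_eukaryote = e,
                             nonmammalian_metazoan = m, vertebrate = 1))
    want <- if (p > 5) "U" else if (e >= 1) "E" else if (m >= 1) "M" else "V"
    expect_identical(got, want)
  }
})

test_that("raising prokaryote hits never demotes a Universal call", {
  for (e in c(0, 3)) for (m in c(0, 3)) {
    prev <- classifyProfile(c(prokaryote = 6, nonmetazoan_eukaryote = e,
                              nonmammalian_metazoan = m, vertebrate = 0))
    expect_equal(prev, "U")
    for (p in 7:12)
      expect_equal(classifyProfile(
        c(prokaryote = p, nonmetazoan_eukaryote = e,
          nonmammalian_metazoan = m, vertebrate = 0)), "U")
  }
})

test_that("class composition reports counts and rounded percentages", {
  fx <- loadFixture("gsis69")
  comp <- classComposition(fx)
  expect_equal(comp$count, c(53L, 12L, 2L, 2L))
  expect_equal(comp$percent, c(77L, 17L, 3L, 3L))
  empty <- classComposition(makeRecords(numeric(0),
                                        pathways = character(0),
                                        class = character(0)))
  expect_equal(empty$count, rep(0L, 4))
  one <- classComposition(makeRecords(95))
  expect_equal(one$percent[one$class == "U"], 100L)
})

test_that("composition chi-squared matches closed forms and is scale-invariant", {
  prop <- compareComposition(c(28, 10, 2, 10), c(0.56, 0.20, 0.04, 0.20))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  two <- compareComposition(c(10, 0), c(0.5, 0.5))
  expect_equal(two$chi2, 10)
  expect_equal(two$df, 1L)
  a <- compareComposition(c(53, 12, 2, 2), c(0.56, 0.20, 0.05, 0.19))
  b <- compareComposition(c(53, 12, 2, 2), 7 * c(0.56, 0.20, 0.05, 0.19))
  expect_equal(a$chi2, b$chi2)
  hand <- sum((c(53, 12, 2, 2) - 69 * c(0.56, 0.20, 0.05, 0.19))^2 /
                (69 * c(0.56, 0.20, 0.05, 0.19)))
  expect_equal(a$chi2, hand)
  expect_error(compareComposition(c(5, 5), c(1, 0)), "zero")
  expect_error(compareComposition(c(0, 0), c(0.5, 0.5)), "positive")
})

test_that("shared-homologue clusters are single-linkage components", {
  mk <- function(name, ids) new("HitProfile", protein = name,
                                hits = setNames(rep(1L, 4),
                                                c("prokaryote",
                                                  "nonmetazoan_eukaryote",
                                                  "nonmammalian_metazoan",
                                                  "vertebrate")),
                                homologIds = ids)
  cl <- sharedHomologClusters(list(mk("A", c("h1", "h2", "h3")),
                                   mk("B", c("h1", "h2", "h3")),
                                   mk("C", "h9")), minShared = 1)
  expect_equal(length(cl), 2L)
  expect_equal(cl[[1]]$proteins, c("A", "B"))
  expect_equal(cl[[1]]$max_shared, 3L)
  expect_equal(cl[[2]]$proteins, "C")
  ## a chain a-b, b-c links all three even if a and c share nothing
  chain <- sharedHomologClusters(list(mk("a", c("x", "y")),
                                      mk("b", c("y", "z")),
                                      mk("c", "z")), minShared = 1)
  expect_equal(length(chain), 1L)
  expect_equal(chain[[1]]$proteins, c("a", "b", "c"))
  expect_error(sharedHomologClusters(list(mk("a", "x")), minShared = 0),
               ">= 1")
})

test_that("component structure matches a union-find oracle on random profiles", {
  set.seed(77)
  for (rep in 1:20) {
    idSets <- lapply(1:8, function(i)
      sample(sprintf("h%02d", 1:20), sample(0:6, 1)))
    profs <- lapply(1:8, function(i)
      new("HitProfile", protein = sprintf("P%d", i),
          hits = setNames(rep(0L, 4),
                          c("prokaryote", "nonmetazoan_eukaryote",
                            "nonmammalian_metazoan", "vertebrate")),
          homologIds = idSets[[i]]))
    minShared <- sample(1:2, 1)
    got <- sharedHomologClusters(profs, minShared)
    comp <- unionFindOracle(idSets, minShared)
    wantPart <- lapply(split(sprintf("P%d", 1:8), comp), sort)
    gotPart <- lapply(got, function(cl) cl$proteins)
    expect_setequal(lapply(wantPart, paste, collapse = ","),
                    lapply(gotPart, paste, collapse = ","))
  }
})

test_that("the study's duplication-sharing structure emerges from embedded intersections", {
  ## embed the printed intersection cardinalities (31, 207, 89, 80, 7, 2)
  ## as synthetic homologue-id sets and check the components reproduce the
  ## printed groups, structurally
  pool <- function(tag, n) sprintf("%s_%03d", tag, seq_len(n))
  sets <- list(
    IDHa = pool("idh", 31), IDHg = pool("idh", 31),
    IDHcp = pool("idh", 31), IDHcc = pool("idh", 31),
    PDCc = pool("pdc", 207), PDCa = pool("pdc", 207),
    MDH = pool("ldh", 89), LDHa = pool("ldh", 89), LDHb = pool("ldh", 89),
    SOD2m = pool("sod", 80), SOD2e = pool("sod", 80),
    `ETF-QO` = pool("etf", 7), GSSGR = pool("etf", 7),
    PDCb = pool("cox", 2), Cox5a = pool("cox", 2),
    GK = pool("gk", 5))
  profs <- lapply(names(sets), function(nm)
    new("HitProfile", protein = nm,
        hits = setNames(rep(0L, 4),
                        c("prokaryote", "nonmetazoan_eukaryote",
                          "nonmammalian_metazoan", "vertebrate")),
        homologIds = sets[[nm]]))
  cl <- sharedHomologClusters(profs, minShared = 1)
  byProt <- lapply(cl, function(x) x$proteins)
  expect_true(any(vapply(byProt, identical, TRUE,
                         sort(c("IDHa", "IDHcc", "IDHcp", "IDHg")))))
  idh <- cl[[which(vapply(byProt, function(p) "IDHa" %in% p, TRUE))]]
  expect_equal(idh$max_shared, 31L)
  pdc <- cl[[which(vapply(byProt, function(p) "PDCc" %in% p, TRUE))]]
  expect_equal(sort(pdc$proteins), c("PDCa", "PDCc"))
  expect_equal(pdc$max_shared, 207L)
  expect_true(any(vapply(byProt, identical, TRUE, "GK")))  # stays single
})
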