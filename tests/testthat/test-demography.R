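mkPed <- function(...) {
  rows <- list(...)
  Pedigree(do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], sex = r[[2]], birth = as.Date(r[[3]]),
      death = as.Date(NA), mother = r[[4]], father = r[[5]],
      stringsAsFactors = FALSE)
  })))
}

test_that("kinship classes follow the stated precedence", {
  ped <- mkPed(
    list("mom", "F", "2000-01-01", NA, NA),
    list("dad", "M", "1999-01-01", NA, NA),
    list("sire2", "M", "1999-06-01", NA, NA),
    list("dau1", "F", "2005-01-01", "mom", "dad"),
    list("dau2", "F", "2006-01-01", "mom", "dad"),
    list("half_m", "F", "2007-01-01", "mom", "sire2"),
    list("half_p", "M", "2008-01-01", NA, "dad"),
    list("son", "M", "2009-01-01", "mom", "dad"),
    list("other", "F", "2005-06-01", NA, NA)
  )
  expect_equal(kinshipClass(ped, "dau1", "dau2"), "full_sibling")
  expect_equal(kinshipClass(ped, "dau1", "half_m"), "maternal_half_sibling")
  expect_equal(kinshipClass(ped, "dau1", "half_p"), "paternal_half_sibling")
  expect_equal(kinshipClass(ped, "mom", "dau1"), "parent_offspring")
  expect_equal(kinshipClass(ped, "dau1", "mom"), "parent_offspring")
  ## mother-son is not a mother-daughter link; they share no other parents
  expect_equal(kinshipClass(ped, "mom", "son"), "distant")
  expect_equal(kinshipClass(ped, "dau1", "other"), "distant")
  ## unknown parents never match
  expect_equal(kinshipClass(ped, "other", "half_p"), "distant")
  expect_error(kinshipClass(ped, "dau1", "dau1"), "differ")
  expect_error(kinshipClass(ped, "dau1", "ghost"), "missing")
})

test_that("kinship table matches the enumeration oracle on a random pedigree", {
  ped <- randPedigree(50, seed = 77)
  df <- pedigreeTable(ped)
  set.seed(78)
  dy <- t(replicate(120, sample(df$id, 2L)))
  got <- kinshipTable(ped, data.frame(id_a = dy[, 1L], id_b = dy[, 2L]))
  want <- vapply(seq_len(nrow(dy)),
    function(r) oracle_kinship(df, dy[r, 1L], dy[r, 2L]), "")
  expect_equal(got, want)
  ## symmetry of the class (direction only matters inside parent_offspring)
  got_rev <- kinshipTable(ped, data.frame(id_a = dy[, 2L], id_b = dy[, 1L]))
  expect_equal(got, got_rev)
})

test_that("shared days sum interval overlaps inside the window", {
  w <- as.Date(c("2016-08-17", "2018-08-17")) # a 730-day window
  rec <- data.frame(
    id = c("a", "b"), harem = "H",
    start = as.Date("2015-01-01"), end = as.Date(NA),
    role = "adult_female", stringsAsFactors = FALSE
  )
  expect_equal(sharedDays(MembershipHistory(rec), "a", "b", w), 730)

  rec2 <- rbind(
    data.frame(id = "a", harem = c("H", "Z", "K"),
      start = as.Date(c("2016-09-01", "2016-12-10", "2017-06-01")),
      end = as.Date(c("2016-12-10", "2017-06-01", "2017-07-21")),
      role = "adult_female"),
    data.frame(id = "b", harem = c("H", "Q", "K"),
      start = as.Date(c("2016-09-01", "2016-12-10", "2017-06-01")),
      end = as.Date(c("2016-12-10", "2017-06-01", "2017-07-21")),
      role = "adult_female")
  )
  ## together 100 days in H, apart, then 50 days in K
  rec2$end[rec2$harem == "H"] <- as.Date("2016-09-01") + 100
  rec2$start[rec2$harem %in% c("Z", "Q")] <- as.Date("2016-09-01") + 100
  rec2$end[rec2$harem == "K"] <- as.Date("2017-06-01") + 50
  expect_equal(sharedDays(MembershipHistory(rec2), "a", "b", w), 150)

  ## randomised histories vs the day-by-day oracle
  for (case in 1:8) {
    mh <- randMembership(c("a", "b", "c"), seed = 800 + case)
    w2 <- as.Date(c("2011-03-01", "2014-03-01"))
    for (pair in list(c("a", "b"), c("a", "c"))) {
      expect_equal(
        sharedDays(mh, pair[1L], pair[2L], w2),
        oracle_shared_days(membershipRecords(mh), pair[1L], pair[2L], w2)
      )
    }
  }
})

test_that("shared days respect the window bounds and are additive", {
  mh <- randMembership(c("a", "b"), seed = 12)
  w <- as.Date(c("2011-01-01", "2013-01-01"))
  mid <- as.Date("2012-02-15")
  total <- sharedDays(mh, "a", "b", w)
  expect_lte(total, as.numeric(w[2L] - w[1L]))
  expect_equal(total,
    sharedDays(mh, "a", "b", c(w[1L], mid)) +
      sharedDays(mh, "a", "b", c(mid, w[2L])))
  expect_error(sharedDays(mh, "a", "b", rev(w)), "window")
})

test_that("stallion subadult co-residence counts only subadult spells", {
  rec <- rbind(
    data.frame(id = c("s1", "s2"), harem = "NAT",
      start = as.Date("2000-05-01"), end = as.Date("2000-05-01") + 400,
      role = "subadult"),
    data.frame(id = c("s1", "s2"), harem = c("HA", "HB"),
      start = as.Date("2002-01-01"), end = as.Date(NA),
      role = "harem_stallion")
  )
  mh <- MembershipHistory(rec)
  ped <- mkPed(list("s1", "M", "1998-05-01", NA, NA),
    list("s2", "M", "1998-06-01", NA, NA))
  expect_equal(stallionSubadultSharedDays(mh, ped, "s1", "s2"), 400)

  ## adults-only overlap contributes nothing
  rec2 <- data.frame(id = c("s1", "s2"), harem = "HC",
    start = as.Date("2005-01-01"), end = as.Date("2006-01-01"),
    role = "adult_female")
  expect_equal(stallionSubadultSharedDays(
    MembershipHistory(rec2), ped, "s1", "s2"), 0)
})

test_that("harem-pair familiarity sums cross-pair shared days", {
  rec <- data.frame(
    id = c("f1", "f2"), harem = "OLD",
    start = as.Date("2016-01-01"), end = as.Date("2016-01-01") + 200,
    role = "adult_female", stringsAsFactors = FALSE
  )
  mh <- MembershipHistory(rec)
  w <- as.Date(c("2015-01-01", "2018-01-01"))
  expect_equal(haremPairFamiliarity(mh, "f1", "f2", w), 200)
  expect_equal(haremPairFamiliarity(mh, "f1", "f3", w), 0)
  ## nested-loop oracle on random histories
  mh2 <- randMembership(c("f1", "f2", "g1", "g2"), seed = 44)
  manual <- 0
  for (a in c("f1", "f2")) {
    for (b in c("g1", "g2")) {
      manual <- manual +
        oracle_shared_days(membershipRecords(mh2), a, b, w)
    }
  }
  expect_equal(haremPairFamiliarity(mh2, c("f1", "f2"), c("g1", "g2"), w),
    manual)
})

test_that("transfer counting compares endpoint snapshots, undirected", {
  mk <- function(id, harems, dates, roles = "adult_female") {
    data.frame(id = id, harem = harems,
      start = as.Date(dates),
      end = c(as.Date(dates)[-1L], as.Date(NA)),
      role = roles, stringsAsFactors = FALSE)
  }
  rec <- rbind(
    mk("f1", c("NAT1", "A", "B"), c("2000-01-01", "2005-01-01", "2017-03-01")),
    mk("f2", c("NAT2", "B", "A"), c("2000-01-01", "2005-02-01", "2017-05-01")),
    mk("f3", c("NAT3", "A"), c("2000-01-01", "2005-03-01"))
  )
  mh <- MembershipHistory(rec)
  t0 <- as.Date("2016-09-01")
  t1 <- as.Date("2018-09-01")
  tr <- countTransfers(mh, t0, t1)
  ## one female A->B and one B->A: two changes for the unordered pair
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$transfers, 2L)
  expect_setequal(c(tr$harem_a, tr$harem_b), c("A", "B"))

  ## no composition change
  expect_equal(nrow(countTransfers(mh, as.Date("2010-01-01"),
    as.Date("2012-01-01"))), 0L)

  ## natal dispersal is excluded
  rec_nat <- mk("y1", c("NATY", "C"), c("2015-06-01", "2017-06-01"))
  mh2 <- MembershipHistory(rbind(rec, rec_nat))
  tr2 <- countTransfers(mh2, t0, t1)
  expect_equal(sum(tr2$transfers), 2L)

  ## female absent from one snapshot is skipped with a message
  rec_gap <- mk("g1", "D", "2017-01-01")
  mh3 <- MembershipHistory(rbind(rec, rec_gap))
  expect_message(countTransfers(mh3, t0, t1), "absent from one snapshot")

  ## event-scan variant counts the same single-step moves
  tre <- countTransfers(mh, t0, t1, method = "events")
  expect_equal(tre$transfers, 2L)
})

test_that("lineage links, splits, merges and boundaries follow the rules", {
  snap <- function(year, harem, ids) data.frame(year = year, harem = harem,
    id = ids, stringsAsFactors = FALSE)

  ## plain continuation: jaccard 3/5 with 3 common adults
  lin <- haremLineage(rbind(
    snap(1L, "X", c("S1", "F1", "F2", "F3")),
    snap(2L, "X", c("S1", "F1", "F2", "F4"))
  ))
  l <- lineageTable(lin)
  expect_equal(l$ancestor[l$year == 2L], "X")
  expect_equal(l$jaccard[l$year == 2L], 0.6)
  expect_equal(l$n_common[l$year == 2L], 3L)
  expect_false(l$new[l$year == 2L])
  expect_false(l$ended_after[l$year == 1L])

  ## one common adult is below the two-common floor: new harem
  lin2 <- haremLineage(rbind(
    snap(1L, "X", c("S1", "F1", "F2")),
    snap(2L, "Y", c("S1", "G1", "G2"))
  ))
  l2 <- lineageTable(lin2)
  expect_true(l2$new[l2$year == 2L])
  expect_true(is.na(l2$ancestor[l2$year == 2L]))
  expect_true(l2$ended_after[l2$year == 1L])

  ## exactly two common adults: linked
  lin2b <- haremLineage(rbind(
    snap(1L, "X", c("S1", "F1", "F2")),
    snap(2L, "Y", c("S1", "F1", "G2"))
  ))
  expect_equal(lineageTable(lin2b)$ancestor[2L], "X")

  ## split: the descendant with more common adults keeps the lineage
  lin3 <- haremLineage(rbind(
    snap(1L, "A", c("s", "a", "b", "c", "d", "e")),
    snap(2L, "A1", c("s", "a", "b", "x")),
    snap(2L, "A2", c("d", "e", "y"))
  ))
  l3 <- lineageTable(lin3)
  expect_equal(l3$ancestor[l3$harem == "A1" & l3$year == 2L], "A")
  expect_true(l3$new[l3$harem == "A2" & l3$year == 2L])

  ## merge: tie on jaccard and common size -> oldest (then lexicographic)
  lin4 <- haremLineage(rbind(
    snap(1L, "P", c("a", "b", "c")),
    snap(1L, "Q", c("d", "e", "f")),
    snap(2L, "M", c("a", "b", "d", "e"))
  ))
  expect_equal(lineageTable(lin4)$ancestor[3L], "P")

  ## determinism
  again <- haremLineage(rbind(
    snap(1L, "A", c("s", "a", "b", "c", "d", "e")),
    snap(2L, "A1", c("s", "a", "b", "x")),
    snap(2L, "A2", c("d", "e", "y"))
  ))
  expect_identical(lineageTable(again), l3)

  expect_error(haremLineage(rbind(snap(1L, "X", "a"), snap(1L, "Y", "a"))),
    "two harems")
})

test_that("lineage start dates give harem ages in whole years", {
  snaps <- rbind(
    data.frame(year = 2010L, harem = "X", id = c("s", "f1", "f2")),
    data.frame(year = 2011L, harem = "X", id = c("s", "f1", "f2")),
    data.frame(year = 2012L, harem = "X", id = c("s", "f1", "f3"))
  )
  lin <- haremLineage(snaps)
  expect_equal(haremAge(lin, "X", 2012L), 2L)
  expect_equal(haremAge(lin, "X", 2010L), 0L)
  expect_error(haremAge(lin, "Z", 2012L), "no lineage row")
})

test_that("stallion experience sums harem-stallion tenure in years", {
  rec <- data.frame(
    id = "s", harem = c("A", "B"),
    start = as.Date(c("2000-01-01", "2006-01-01")),
    end = as.Date(c("2004-01-01", "2009-01-01")),
    role = "harem_stallion", stringsAsFactors = FALSE
  )
  mh <- MembershipHistory(rec)
  ## 2000-2004 is 1461 days = exactly 4 mean years
  expect_equal(stallionExperience(mh, "s", as.Date("2004-06-01")), 4)
  expect_equal(stallionExperience(mh, "s", as.Date("2010-01-01")),
    (1461 + 1096) / 365.25)
  ## cutoff clips an ongoing tenure
  expect_equal(stallionExperience(mh, "s", as.Date("2001-01-01")),
    366 / 365.25)
  expect_equal(stallionExperience(mh, "nobody", as.Date("2010-01-01")), 0)
})

test_that("sibling cohabitation statistic counts co-resident sibling dyads", {
  ped <- mkPed(
    list("m1", "F", "2000-01-01", NA, NA),
    list("f1", "F", "2005-01-01", "m1", NA),
    list("f2", "F", "2006-01-01", "m1", NA),
    list("f3", "F", "2006-05-01", NA, NA),
    list("f4", "F", "2007-01-01", NA, NA)
  )
  expect_equal(siblingCohabitationStat(ped,
    c(f1 = "A", f2 = "A", f3 = "B", f4 = "B")), 1L)
  expect_equal(siblingCohabitationStat(ped,
    c(f1 = "A", f2 = "B", f3 = "A", f4 = "B")), 0L)
  expect_equal(siblingCohabitationStat(ped,
    c(f3 = "A", f4 = "A")), 0L)
})

test_that("membership and pedigree CSV dialects round-trip", {
  pop <- simulatePopulation(populationConfig(n_years = 5L), seed = 2)
  fp <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  writePedigree(pop$pedigree, fp)
  writeMembership(pop$membership, fm)
  expect_equal(pedigreeTable(readPedigree(fp)), pedigreeTable(pop$pedigree))
  expect_equal(membershipRecords(readMembership(fm)),
    membershipRecords(pop$membership))
})
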