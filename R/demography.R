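## Long-term-monitoring computations: pedigree kinship classes, familiarity
## (shared harem days), female transfer counts, Jaccard-based harem lineage
## and age, and stallion harem-keeping experience.

#' Construct / read a Pedigree
#'
#' @param individuals data.frame with columns `id`, `sex` ("F"/"M"),
#'   `birth_date`, `death_date`, `mother_id`, `father_id` (the CSV dialect),
#'   or the internal names `birth`, `death`, `mother`, `father`.
#' @return A [Pedigree-class].
#' @export
Pedigree <- function(individuals) {
  d <- as.data.frame(individuals)
  ren <- c(birth_date = "birth", death_date = "death", mother_id = "mother",
    father_id = "father")
  for (from in names(ren)) {
    if (from %in% names(d)) names(d)[names(d) == from] <- ren[[from]]
  }
  d$id <- as.character(d$id)
  for (col in c("mother", "father")) {
    d[[col]] <- as.character(d[[col]])
    d[[col]][d[[col]] %in% c("", "NA")] <- NA_character_
  }
  d$birth <- as.Date(d$birth)
  d$death <- as.Date(if (is.null(d$death)) rep(NA, nrow(d)) else d$death)
  rownames(d) <- NULL
  new("Pedigree", individuals = d[, c("id", "sex", "birth", "death",
    "mother", "father")])
}

#' @rdname Pedigree
#' @param path CSV path (`id,sex,birth_date,death_date,mother_id,father_id`,
#'   ISO-8601 dates).
#' @export
readPedigree <- function(path) {
  Pedigree(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a Pedigree to its CSV dialect
#' @param x a [Pedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(x, path) {
  d <- pedigreeTable(x)
  write.csv(data.frame(id = d$id, sex = d$sex, birth_date = d$birth,
    death_date = d$death, mother_id = d$mother, father_id = d$father),
    path, row.names = FALSE)
  invisible(path)
}

#' Construct / read a MembershipHistory
#'
#' @param records data.frame with columns `id`, `harem_id` (or `harem`),
#'   `start_date`/`start`, `end_date`/`end` (NA = ongoing), `role`.
#' @return A [MembershipHistory-class].
#' @export
MembershipHistory <- function(records) {
  r <- as.data.frame(records)
  ren <- c(harem_id = "harem", start_date = "start", end_date = "end")
  for (from in names(ren)) {
    if (from %in% names(r)) names(r)[names(r) == from] <- ren[[from]]
  }
  r$id <- as.character(r$id)
  r$harem <- as.character(r$harem)
  r$start <- as.Date(r$start)
  r$end <- as.Date(if (is.null(r$end)) rep(NA, nrow(r)) else r$end)
  r <- r[order(r$id, r$start), c("id", "harem", "start", "end", "role")]
  rownames(r) <- NULL
  new("MembershipHistory", records = r)
}

#' @rdname MembershipHistory
#' @param path CSV path (`id,harem_id,start_date,end_date,role`).
#' @export
readMembership <- function(path) {
  MembershipHistory(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a MembershipHistory to its CSV dialect
#' @param x a [MembershipHistory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMembership <- function(x, path) {
  r <- membershipRecords(x)
  write.csv(data.frame(id = r$id, harem_id = r$harem, start_date = r$start,
    end_date = r$end, role = r$role), path, row.names = FALSE)
  invisible(path)
}

#' Pedigree kinship class of a dyad
#'
#' Classes, in precedence order: `parent_offspring` (mother-daughter link),
#' `full_sibling` (both parents known and shared), `maternal_half_sibling`,
#' `paternal_half_sibling`, `distant`. Unknown parents never match.
#'
#' @param ped a [Pedigree-class].
#' @param a,b individual ids (a != b).
#' @return a single class label.
#' @export
kinshipClass <- function(ped, a, b) {
  if (a == b) stop("a and b must differ")
  d <- pedigreeTable(ped)
  ia <- match(a, d$id)
  ib <- match(b, d$id)
  if (is.na(ia) || is.na(ib)) {
    stop("id(s) missing from pedigree: ",
      paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  }
  mo <- setNames(d$mother, d$id)
  fa <- setNames(d$father, d$id)
  sex <- setNames(d$sex, d$id)
  if ((!is.na(mo[b]) && mo[b] == a && sex[b] == "F") ||
    (!is.na(mo[a]) && mo[a] == b && sex[a] == "F")) {
    return("parent_offspring")
  }
  same_mo <- !is.na(mo[a]) && !is.na(mo[b]) && mo[a] == mo[b]
  same_fa <- !is.na(fa[a]) && !is.na(fa[b]) && fa[a] == fa[b]
  if (same_mo && same_fa) return("full_sibling")
  if (same_mo) return("maternal_half_sibling")
  if (same_fa) return("paternal_half_sibling")
  "distant"
}

#' Kinship classes for a table of dyads
#'
#' Vectorised [kinshipClass()].
#'
#' @param ped a [Pedigree-class].
#' @param dyads data.frame with columns `id_a`, `id_b`.
#' @return character vector of classes aligned with `dyads` rows.
#' @export
kinshipTable <- function(ped, dyads) {
  d <- pedigreeTable(ped)
  mo <- setNames(d$mother, d$id)
  fa <- setNames(d$father, d$id)
  sex <- setNames(d$sex, d$id)
  a <- dyads$id_a
  b <- dyads$id_b
  if (any(!c(a, b) %in% d$id)) stop("dyad ids missing from pedigree")
  po <- (!is.na(mo[b]) & mo[b] == a & sex[b] == "F") |
    (!is.na(mo[a]) & mo[a] == b & sex[a] == "F")
  same_mo <- !is.na(mo[a]) & !is.na(mo[b]) & mo[a] == mo[b]
  same_fa <- !is.na(fa[a]) & !is.na(fa[b]) & fa[a] == fa[b]
  out <- rep("distant", nrow(dyads))
  out[same_fa] <- "paternal_half_sibling"
  out[same_mo] <- "maternal_half_sibling"
  out[same_mo & same_fa] <- "full_sibling"
  out[po] <- "parent_offspring"
  unname(out)
}

## overlap in days of half-open intervals [s1,e1) x [s2,e2), NA end = open
.intervalOverlapDays <- function(s1, e1, s2, e2, ws = -Inf, we = Inf) {
  e1 <- ifelse(is.na(e1), Inf, as.numeric(e1))
  e2 <- ifelse(is.na(e2), Inf, as.numeric(e2))
  lo <- pmax(as.numeric(s1), as.numeric(s2), ws)
  hi <- pmin(e1, e2, we)
  pmax(0, hi - lo)
}

#' Shared harem days of a dyad within a window
#'
#' Total number of days inside `window` on which both individuals are
#' recorded in the same harem, summed over all common harems. Intervals are
#' half-open `[start, end)` and membership is piecewise-constant between
#' records.
#'
#' @param mh a [MembershipHistory-class].
#' @param a,b individual ids.
#' @param window length-2 Date vector (start, end), or NULL for all time.
#' @return days (numeric).
#' @export
sharedDays <- function(mh, a, b, window = NULL) {
  r <- membershipRecords(mh)
  ws <- if (is.null(window)) -Inf else as.numeric(as.Date(window[1L]))
  we <- if (is.null(window)) Inf else as.numeric(as.Date(window[2L]))
  if (we < ws) stop("window end before start")
  ra <- r[r$id == a, , drop = FALSE]
  rb <- r[r$id == b, , drop = FALSE]
  if (nrow(ra) == 0L || nrow(rb) == 0L) return(0)
  total <- 0
  for (i in seq_len(nrow(ra))) {
    same <- rb[rb$harem == ra$harem[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    total <- total + sum(.intervalOverlapDays(
      ra$start[i], ra$end[i], same$start, same$end, ws, we))
  }
  total
}

#' Shared subadult days of a stallion pair
#'
#' Days the pair spent in the same harem while both held the subadult role
#' (co-residence during young age in a natal harem).
#'
#' @param mh a [MembershipHistory-class].
#' @param ped a [Pedigree-class] (both individuals must be present).
#' @param a,b individual ids.
#' @return days (numeric).
#' @export
stallionSubadultSharedDays <- function(mh, ped, a, b) {
  d <- pedigreeTable(ped)
  if (any(!c(a, b) %in% d$id)) stop("id(s) missing from pedigree")
  r <- membershipRecords(mh)
  sub <- r[r$role == "subadult", , drop = FALSE]
  sharedDays(new("MembershipHistory", records = sub), a, b)
}

#' Familiarity of the adult females of two harems
#'
#' The sum of shared harem days over all cross pairs of adult females from
#' the two rosters, within the window.
#'
#' @param mh a [MembershipHistory-class].
#' @param females_a,females_b adult-female ids of the two harems.
#' @param window length-2 Date vector.
#' @return days (numeric).
#' @export
haremPairFamiliarity <- function(mh, females_a, females_b, window) {
  total <- 0
  for (a in females_a) {
    for (b in females_b) total <- total + sharedDays(mh, a, b, window)
  }
  total
}

#' Snapshot of harem membership at a date
#'
#' @param mh a [MembershipHistory-class].
#' @param date a Date; records with `start <= date < end` apply.
#' @return data.frame `id`, `harem`, `role`.
#' @export
snapshotAt <- function(mh, date) {
  r <- membershipRecords(mh)
  date <- as.numeric(as.Date(date))
  endn <- ifelse(is.na(r$end), Inf, as.numeric(r$end))
  k <- as.numeric(r$start) <= date & date < endn
  out <- r[k, c("id", "harem", "role")]
  rownames(out) <- NULL
  out
}

## natal harem = harem of the individual's earliest membership record
.natalHarem <- function(mh) {
  r <- membershipRecords(mh)
  r <- r[order(r$id, r$start), ]
  first <- !duplicated(r$id)
  setNames(r$harem[first], r$id[first])
}

#' Count female transfers between harem pairs
#'
#' Compares each female's harem at the two window endpoints; a female in
#' harem A at the start and B at the end adds one transfer to the unordered
#' pair \{A, B\}, regardless of direction. Moves out of the natal harem
#' (the young female's first breeding dispersal) are excluded. Females
#' absent from either snapshot are skipped with a message. With
#' `method = "events"` every intermediate membership change inside the
#' window is counted instead.
#'
#' @param mh a [MembershipHistory-class].
#' @param t0,t1 window endpoint Dates (e.g. two years apart).
#' @param females ids of the females to consider; default: all individuals
#'   holding the `adult_female` role at either endpoint.
#' @param method `"endpoint"` (snapshot comparison, the default) or
#'   `"events"`.
#' @return data.frame `harem_a`, `harem_b`, `transfers` (unordered pairs
#'   with at least one transfer).
#' @export
countTransfers <- function(mh, t0, t1, females = NULL,
                           method = c("endpoint", "events")) {
  method <- match.arg(method)
  t0 <- as.Date(t0)
  t1 <- as.Date(t1)
  s0 <- snapshotAt(mh, t0)
  s1 <- snapshotAt(mh, t1)
  if (is.null(females)) {
    females <- union(s0$id[s0$role == "adult_female"],
      s1$id[s1$role == "adult_female"])
  }
  natal <- .natalHarem(mh)
  pairs <- character()
  if (method == "endpoint") {
    h0 <- setNames(s0$harem, s0$id)
    h1 <- setNames(s1$harem, s1$id)
    skipped <- 0L
    for (f in females) {
      if (!f %in% names(h0) || !f %in% names(h1)) {
        skipped <- skipped + 1L
        next
      }
      if (h0[f] == h1[f]) next
      if (!is.na(natal[f]) && h0[f] == natal[f]) next # natal dispersal
      pairs <- c(pairs, paste(sort(c(h0[f], h1[f])), collapse = "\r"))
    }
    if (skipped) {
      message(skipped, " female(s) absent from one snapshot; skipped")
    }
  } else {
    r <- membershipRecords(mh)
    for (f in females) {
      rf <- r[r$id == f, , drop = FALSE]
      rf <- rf[order(rf$start), ]
      if (nrow(rf) < 2L) next
      for (i in 2:nrow(rf)) {
        move_date <- rf$start[i]
        if (move_date <= t0 || move_date > t1) next
        if (rf$harem[i] == rf$harem[i - 1L]) next
        if (!is.na(natal[f]) && rf$harem[i - 1L] == natal[f]) next
        pairs <- c(pairs, paste(sort(c(rf$harem[i - 1L], rf$harem[i])),
          collapse = "\r"))
      }
    }
  }
  if (!length(pairs)) {
    return(data.frame(harem_a = character(), harem_b = character(),
      transfers = integer()))
  }
  tab <- table(pairs)
  ks <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    harem_a = vapply(ks, `[`, "", 1L), harem_b = vapply(ks, `[`, "", 2L),
    transfers = as.integer(tab), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Yearly adult snapshots from a membership history
#'
#' One snapshot per year at the given month/day (the record prior to 1
#' September convention corresponds to `"09-01"`): the adult members
#' (adult females and the harem stallion) of each harem.
#'
#' @param mh a [MembershipHistory-class].
#' @param years integer vector of years.
#' @param month_day snapshot date within the year, `"MM-DD"`.
#' @return data.frame `year`, `harem`, `id` (adults only).
#' @export
yearlySnapshots <- function(mh, years, month_day = "09-01") {
  rows <- lapply(years, function(y) {
    s <- snapshotAt(mh, as.Date(paste0(y, "-", month_day)))
    s <- s[s$role %in% c("adult_female", "harem_stallion"), , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    data.frame(year = y, harem = s$harem, id = s$id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Link yearly harem snapshots into lineages (Jaccard rule)
#'
#' The ancestor of a harem in year i is the year i-1 harem with the maximal
#' Jaccard index between adult member sets, requiring at least two common
#' adults. If one year i-1 harem is claimed by several year-i harems, the
#' claimant with the most common individuals keeps it; at equal common size
#' the oldest claimant (earliest lineage start, then lexicographic harem id)
#' wins, and the losers are new harems. A harem-year without an ancestor
#' starts a new lineage at that year's snapshot date; a harem-year without a
#' descendant is flagged ended.
#'
#' @param snapshots data.frame `year`, `harem`, `id` (adult members), e.g.
#'   from [yearlySnapshots()].
#' @param snapshot_dates optional named Date vector (names = years); default
#'   1 September of each year.
#' @return A [HaremLineage-class].
#' @export
haremLineage <- function(snapshots, snapshot_dates = NULL) {
  years <- sort(unique(snapshots$year))
  if (is.null(snapshot_dates)) {
    snapshot_dates <- setNames(as.Date(paste0(years, "-09-01")),
      as.character(years))
  }
  key <- function(y, h) paste(y, h, sep = ":")
  if (anyDuplicated(snapshots[, c("year", "harem", "id")])) {
    stop("duplicate (year, harem, id) rows in snapshots")
  }
  if (anyDuplicated(snapshots[, c("year", "id")])) {
    stop("an individual appears in two harems of the same yearly snapshot")
  }
  members <- list()
  for (y in years) {
    sub <- snapshots[snapshots$year == y, , drop = FALSE]
    for (h in unique(sub$harem)) {
      members[[key(y, h)]] <- sort(sub$id[sub$harem == h])
    }
  }
  lineage <- NULL
  start <- list() # key -> Date of lineage start
  for (yi in seq_along(years)) {
    y <- years[yi]
    hs <- unique(snapshots$harem[snapshots$year == y])
    if (anyDuplicated(hs)) stop("duplicate harem ids within year ", y)
    if (yi == 1L) {
      for (h in hs) start[[key(y, h)]] <- unname(snapshot_dates[as.character(y)])
      lineage <- rbind(lineage, data.frame(
        harem = hs, year = y, ancestor = NA_character_,
        n_common = NA_integer_, jaccard = NA_real_,
        start_date = unname(snapshot_dates[as.character(y)]),
        new = TRUE, stringsAsFactors = FALSE
      ))
      next
    }
    yprev <- years[yi - 1L]
    prev_hs <- unique(snapshots$harem[snapshots$year == yprev])
    ## best candidate ancestor per year-y harem
    claims <- data.frame(harem = character(), ancestor = character(),
      n_common = integer(), jaccard = numeric(), stringsAsFactors = FALSE)
    for (h in hs) {
      mem <- members[[key(y, h)]]
      best <- NULL
      for (g in prev_hs) {
        pm <- members[[key(yprev, g)]]
        nc <- length(intersect(mem, pm))
        if (nc < 2L) next
        jac <- nc / length(union(mem, pm))
        if (is.null(best) || jac > best$jaccard + 1e-12 ||
          (abs(jac - best$jaccard) <= 1e-12 && nc > best$n_common) ||
          (abs(jac - best$jaccard) <= 1e-12 && nc == best$n_common &&
            .lineageOlder(g, best$ancestor, yprev, start, key))) {
          best <- list(ancestor = g, n_common = nc, jaccard = jac)
        }
      }
      if (!is.null(best)) {
        claims <- rbind(claims, data.frame(harem = h,
          ancestor = best$ancestor, n_common = best$n_common,
          jaccard = best$jaccard, stringsAsFactors = FALSE))
      }
    }
    ## resolve ancestors claimed by several descendants
    keep <- rep(TRUE, nrow(claims))
    for (g in unique(claims$ancestor)) {
      idx <- which(claims$ancestor == g)
      if (length(idx) <= 1L) next
      nc <- claims$n_common[idx]
      cand <- idx[nc == max(nc)]
      if (length(cand) > 1L) {
        ## oldest claimant: earliest lineage start, then lexicographic id
        starts <- vapply(claims$harem[cand], function(h) {
          s <- start[[key(yprev, h)]]
          if (is.null(s)) Inf else as.numeric(s)
        }, numeric(1L))
        cand <- cand[order(starts, claims$harem[cand])][1L]
      } else {
        cand <- cand[1L]
      }
      keep[setdiff(idx, cand)] <- FALSE
    }
    claims <- claims[keep, , drop = FALSE]
    anc <- setNames(claims$ancestor, claims$harem)
    ncm <- setNames(claims$n_common, claims$harem)
    jcc <- setNames(claims$jaccard, claims$harem)
    for (h in hs) {
      if (h %in% names(anc)) {
        ps <- start[[key(yprev, anc[h])]]
        start[[key(y, h)]] <- if (is.null(ps))
          unname(snapshot_dates[as.character(y)]) else ps
      } else {
        start[[key(y, h)]] <- unname(snapshot_dates[as.character(y)])
      }
    }
    lineage <- rbind(lineage, data.frame(
      harem = hs, year = y,
      ancestor = ifelse(hs %in% names(anc), anc[hs], NA_character_),
      n_common = ifelse(hs %in% names(ncm), ncm[hs], NA_integer_),
      jaccard = ifelse(hs %in% names(jcc), jcc[hs], NA_real_),
      start_date = as.Date(vapply(hs, function(h)
        as.numeric(start[[key(y, h)]]), numeric(1L)), origin = "1970-01-01"),
      new = !hs %in% names(anc), stringsAsFactors = FALSE
    ))
  }
  ## ended flag: no descendant links to this harem-year
  lineage$ended_after <- NA
  for (yi in seq_along(years)[-length(years)]) {
    y <- years[yi]
    ynext <- years[yi + 1L]
    desc <- lineage$ancestor[lineage$year == ynext]
    here <- lineage$year == y
    lineage$ended_after[here] <- !lineage$harem[here] %in% desc
  }
  rownames(lineage) <- NULL
  new("HaremLineage", lineage = lineage, members = members)
}

.lineageOlder <- function(g, ref, yprev, start, key) {
  sg <- start[[key(yprev, g)]]
  sr <- start[[key(yprev, ref)]]
  sg <- if (is.null(sg)) Inf else as.numeric(sg)
  sr <- if (is.null(sr)) Inf else as.numeric(sr)
  sg < sr || (sg == sr && g < ref)
}

#' Harem age at a date
#'
#' Whole years elapsed since the lineage start of the harem's chain, at the
#' given year's row.
#'
#' @param lin a [HaremLineage-class].
#' @param harem harem id.
#' @param year snapshot year of interest.
#' @param at Date at which the age is evaluated; default the year's
#'   1 September snapshot date.
#' @return age in whole years (integer).
#' @export
haremAge <- function(lin, harem, year, at = NULL) {
  l <- lineageTable(lin)
  row <- l[l$harem == harem & l$year == year, , drop = FALSE]
  if (nrow(row) != 1L) stop("no lineage row for ", harem, " in ", year)
  if (is.null(at)) at <- as.Date(paste0(year, "-09-01"))
  as.integer(floor(as.numeric(as.Date(at) - row$start_date) / 365.25))
}

#' Stallion harem-keeping experience
#'
#' Total time (in years of 365.25 days) the male held the harem-stallion
#' position before `at`, summed over all his harems.
#'
#' @param mh a [MembershipHistory-class].
#' @param stallion individual id.
#' @param at cutoff Date.
#' @return years (numeric).
#' @export
stallionExperience <- function(mh, stallion, at) {
  r <- membershipRecords(mh)
  r <- r[r$id == stallion & r$role == "harem_stallion", , drop = FALSE]
  if (nrow(r) == 0L) return(0)
  days <- sum(.intervalOverlapDays(r$start, r$end, r$start, r$end,
    we = as.numeric(as.Date(at))))
  days / 365.25
}

#' Number of co-resident sibling adult-female dyads
#'
#' Counts the full- and half-sibling adult-female dyads that currently share
#' a harem — the statistic fed to the roster-reassignment randomisation
#' scheme.
#'
#' @param ped a [Pedigree-class].
#' @param rosters named vector, adult-female id -> harem.
#' @return integer count.
#' @export
siblingCohabitationStat <- function(ped, rosters) {
  ids <- names(rosters)
  if (length(ids) < 2L) return(0L)
  dy <- t(utils::combn(ids, 2L))
  cls <- kinshipTable(ped, data.frame(id_a = dy[, 1L], id_b = dy[, 2L]))
  sib <- cls %in% c("full_sibling", "maternal_half_sibling",
    "paternal_half_sibling")
  sum(sib & rosters[dy[, 1L]] == rosters[dy[, 2L]])
}
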