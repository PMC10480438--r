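## Multi-year synthetic population: yearly cycles of births, deaths,
## dispersals, adult-female transfers, stallion takeovers and harem
## foundations, emitting a Pedigree, a MembershipHistory and an event log
## that serves as ground truth for the demography computations.

#' Population simulation configuration
#'
#' Dispersal age windows follow the species' biology (females leave the
#' natal harem at 2-3 years, males at 2-4 years); the remaining rates are
#' free generator constants giving a stable population with regular harem
#' turnover over a multi-decade run.
#'
#' @param n_years simulated years (default 20).
#' @param n_founder_harems harems at founding (default 8).
#' @param founder_females_per_harem adult females per founding harem
#'   (default 4).
#' @param n_founder_bachelors founding bachelor males (default 6).
#' @param birth_rate per adult female per year (default 0.55).
#' @param death_rate baseline adult yearly mortality (default 0.02; rises
#'   steeply past `old_age`).
#' @param old_age age in years beyond which mortality is elevated
#'   (default 18).
#' @param female_dispersal_age,male_dispersal_age age windows (years) for
#'   natal dispersal, defaults `c(2, 3)` and `c(2, 4)`.
#' @param transfer_rate per adult female per year probability of changing
#'   breeding harem (default 0.07).
#' @param takeover_rate per harem per year probability of a stallion change
#'   (default 0.10).
#' @param new_harem_rate per year probability that a bachelor founds a new
#'   harem with females drawn from one existing harem (default 0.15) —
#'   creates the split events that exercise the lineage rules.
#' @param start_year first calendar year (default 1998).
#' @return validated configuration list (class `population_config`).
#' @export
populationConfig <- function(n_years = 20L, n_founder_harems = 8L,
                             founder_females_per_harem = 4L,
                             n_founder_bachelors = 6L, birth_rate = 0.55,
                             death_rate = 0.02, old_age = 18,
                             female_dispersal_age = c(2, 3),
                             male_dispersal_age = c(2, 4),
                             transfer_rate = 0.07, takeover_rate = 0.10,
                             new_harem_rate = 0.15, start_year = 1998L) {
  cfg <- list(
    n_years = as.integer(n_years),
    n_founder_harems = as.integer(n_founder_harems),
    founder_females_per_harem = as.integer(founder_females_per_harem),
    n_founder_bachelors = as.integer(n_founder_bachelors),
    birth_rate = birth_rate, death_rate = death_rate, old_age = old_age,
    female_dispersal_age = female_dispersal_age,
    male_dispersal_age = male_dispersal_age,
    transfer_rate = transfer_rate, takeover_rate = takeover_rate,
    new_harem_rate = new_harem_rate, start_year = as.integer(start_year)
  )
  rates <- c(cfg$birth_rate, cfg$death_rate, cfg$transfer_rate,
    cfg$takeover_rate, cfg$new_harem_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(c(cfg$female_dispersal_age, cfg$male_dispersal_age) <= 0)) {
    stop("dispersal ages must be positive")
  }
  class(cfg) <- "population_config"
  cfg
}

#' Simulate a multi-year population with full event-log ground truth
#'
#' Runs a yearly cycle of births (mating within harems), deaths, natal
#' dispersals, adult-female transfers, stallion takeovers and occasional
#' harem foundations. Returns the pedigree, the harem-membership interval
#' records, and the raw event log from which kinship classes, shared days,
#' transfer counts, lineage continuations and stallion tenures can be
#' derived independently.
#'
#' @param config a [populationConfig()].
#' @param seed RNG seed.
#' @return list: `pedigree` ([Pedigree-class]), `membership`
#'   ([MembershipHistory-class]), `events` (data.frame `date`, `id`, `type`,
#'   `from`, `to`), `planted` (manifest, empty unless effects are planted).
#' @export
simulatePopulation <- function(config, seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  .withSeed(seed, .simulatePopulationImpl(config))
}

.simulatePopulationImpl <- function(config) {
  y0 <- config$start_year
  founding <- as.Date(paste0(y0, "-05-01"))
  nextid <- 1L
  mkid <- function(n = 1L) {
    out <- sprintf("P%04d", nextid + seq_len(n) - 1L)
    nextid <<- nextid + n
    out
  }
  ## individual state tables (grown by rbind; populations stay small)
  ped <- NULL      # id, sex, birth, death, mother, father
  open <- NULL     # open membership records: id, harem, start, role
  closed <- NULL   # closed membership records incl. end
  events <- NULL
  assign_h <- character() # id -> harem ("" = bachelor / none)
  disp_age <- numeric()   # id -> individually drawn dispersal age
  log_event <- function(date, id, type, from = NA, to = NA, role = NA) {
    events <<- rbind(events, data.frame(date = date, id = id, type = type,
      from = from, to = to, role = role, stringsAsFactors = FALSE))
  }
  open_rec <- function(id, harem, start, role) {
    open <<- rbind(open, data.frame(id = id, harem = harem, start = start,
      role = role, stringsAsFactors = FALSE))
    assign_h[id] <<- harem
  }
  close_rec <- function(id, at) {
    k <- which(open$id == id)
    if (length(k)) {
      closed <<- rbind(closed, cbind(open[k, , drop = FALSE],
        end = rep(at, length(k))))
      open <<- open[-k, , drop = FALSE]
    }
    assign_h[id] <<- ""
  }
  move <- function(id, harem, at, role) {
    close_rec(id, at)
    open_rec(id, harem, at, role)
  }
  add_ind <- function(id, sex, birth, mother = NA, father = NA) {
    ped <<- rbind(ped, data.frame(id = id, sex = sex, birth = birth,
      death = as.Date(NA), mother = mother, father = father,
      stringsAsFactors = FALSE))
  }
  ## founders: stallions + females of breeding age, plus bachelors
  harems <- sprintf("F%02d", seq_len(config$n_founder_harems))
  for (h in harems) {
    sid <- mkid()
    add_ind(sid, "M", founding - round(runif(1, 5, 10) * 365.25))
    open_rec(sid, h, founding, "harem_stallion")
    log_event(founding, sid, "founding", to = h, role = "harem_stallion")
    for (k in seq_len(config$founder_females_per_harem)) {
      fid <- mkid()
      add_ind(fid, "F", founding - round(runif(1, 3, 12) * 365.25))
      open_rec(fid, h, founding, "adult_female")
      log_event(founding, fid, "founding", to = h, role = "adult_female")
    }
  }
  bachelors <- mkid(config$n_founder_bachelors)
  for (b in bachelors) {
    add_ind(b, "M", founding - round(runif(1, 4, 9) * 365.25))
    assign_h[b] <- ""
    log_event(founding, b, "founding")
  }
  new_harem_no <- 0L
  alive <- function() ped$id[is.na(ped$death)]
  stallion_of <- function(h) {
    open$id[open$harem == h & open$role == "harem_stallion"][1L]
  }
  for (yr in seq_len(config$n_years)) {
    year <- y0 + yr - 1L
    cur_harems <- unique(open$harem)
    if (length(cur_harems) == 0L) {
      stop("population extinct before n_years; relax mortality or rates")
    }
    ## 1. births (spring)
    mothers <- open$id[open$role == "adult_female"]
    for (m in mothers) {
      if (runif(1) > config$birth_rate) next
      bdate <- as.Date(paste0(year, "-04-01")) + sample.int(75L, 1L)
      h <- unname(assign_h[m])
      kid <- mkid()
      add_ind(kid, sample(c("F", "M"), 1L), bdate, mother = m,
        father = stallion_of(h))
      open_rec(kid, h, bdate, "subadult")
      disp_age[kid] <- if (ped$sex[ped$id == kid] == "F") {
        runif(1, config$female_dispersal_age[1L], config$female_dispersal_age[2L])
      } else {
        runif(1, config$male_dispersal_age[1L], config$male_dispersal_age[2L])
      }
      log_event(bdate, kid, "birth", to = h, role = "subadult")
    }
    ## 2. natal dispersal
    for (id in names(disp_age)) {
      if (!id %in% open$id) next
      if (open$role[open$id == id] != "subadult") next
      age <- as.numeric(as.Date(paste0(year, "-07-01")) -
        ped$birth[ped$id == id]) / 365.25
      if (age < disp_age[id]) next
      ddate <- as.Date(paste0(year, "-07-01")) + sample.int(45L, 1L)
      h <- unname(assign_h[id])
      if (ped$sex[ped$id == id] == "F") {
        others <- setdiff(unique(open$harem), h)
        ## with a single harem she matures in place instead of dispersing
        to <- if (length(others)) sample(others, 1L) else h
        move(id, to, ddate, "adult_female")
        log_event(ddate, id, "natal_dispersal", from = h, to = to, role = "adult_female")
      } else {
        close_rec(id, ddate)
        log_event(ddate, id, "natal_dispersal", from = h)
      }
    }
    ## 3. adult-female transfers
    for (id in open$id[open$role == "adult_female"]) {
      if (runif(1) > config$transfer_rate) next
      others <- setdiff(unique(open$harem), assign_h[id])
      if (!length(others)) next
      tdate <- as.Date(paste0(year, "-09-01")) + sample.int(20L, 1L)
      from <- unname(assign_h[id])
      to <- sample(others, 1L)
      move(id, to, tdate, "adult_female")
      log_event(tdate, id, "transfer", from = from, to = to, role = "adult_female")
    }
    ## 4. deaths (autumn): draw first, then process in date order so a
    ## doomed bachelor is never promoted to a harem he cannot hold
    doomed <- character()
    ddates <- as.Date(character())
    for (id in alive()) {
      age <- as.numeric(as.Date(paste0(year, "-10-01")) -
        ped$birth[ped$id == id]) / 365.25
      p <- config$death_rate + if (age > config$old_age) 0.25 else 0
      if (age < 1) p <- p + 0.03
      if (runif(1) > p) next
      doomed <- c(doomed, id)
      ddates <- c(ddates, as.Date(paste0(year, "-10-01")) +
        sample.int(60L, 1L))
    }
    for (k in order(ddates)) {
      id <- doomed[k]
      ddate <- ddates[k]
      h <- if (id %in% names(assign_h)) unname(assign_h[id]) else ""
      was_stallion <- !is.na(h) && h != "" &&
        identical(stallion_of(h), id)
      ped$death[ped$id == id] <- ddate
      if (!is.na(h) && h != "") close_rec(id, ddate)
      assign_h <- assign_h[names(assign_h) != id]
      log_event(ddate, id, "death", from = h)
      if (was_stallion) {
        ## succession: an available bachelor takes over, else harem dissolves
        cand <- setdiff(names(assign_h)[assign_h == ""], doomed)
        cand <- cand[ped$sex[match(cand, ped$id)] == "M"]
        cand <- cand[(as.numeric(ddate - ped$birth[match(cand, ped$id)]) /
          365.25) >= 4]
        if (length(cand)) {
          s <- cand[1L]
          open_rec(s, h, ddate + 1L, "harem_stallion")
          log_event(ddate + 1L, s, "takeover_in", to = h, role = "harem_stallion")
        } else if (length(setdiff(unique(open$harem), h))) {
          for (fid in open$id[open$harem == h]) {
            to <- sample(setdiff(unique(open$harem), h), 1L)
            role <- open$role[open$id == fid]
            move(fid, to, ddate + 1L, role)
            log_event(ddate + 1L, fid, "transfer", from = h, to = to,
              role = role)
          }
        }
      }
    }
    ## 5. stallion takeovers (drawn per harem, processed in date order so a
    ## freshly deposed stallion cannot appear in an earlier-dated takeover)
    tk_harems <- unique(open$harem)
    tk_harems <- tk_harems[runif(length(tk_harems)) <= config$takeover_rate]
    if (length(tk_harems)) {
      tdates <- as.Date(paste0(year, "-12-02")) +
        sample.int(10L, length(tk_harems), replace = TRUE)
      for (k in order(tdates)) {
        h <- tk_harems[k]
        tdate <- tdates[k]
        cand <- names(assign_h)[assign_h == ""]
        cand <- cand[ped$sex[match(cand, ped$id)] == "M"]
        cand <- cand[(as.numeric(tdate - ped$birth[match(cand, ped$id)]) /
          365.25) >= 4]
        if (!length(cand)) next
        old <- stallion_of(h)
        if (!is.na(old)) {
          close_rec(old, tdate)
          log_event(tdate, old, "takeover_out", from = h)
        }
        s <- if (length(cand) == 1L) cand else sample(cand, 1L)
        open_rec(s, h, tdate, "harem_stallion")
        log_event(tdate, s, "takeover_in", to = h, role = "harem_stallion")
      }
    }
    ## 6. new harem foundation (split): a bachelor leaves with 2-3 females
    ## of one donor harem
    if (runif(1) < config$new_harem_rate) {
      cand <- names(assign_h)[assign_h == ""]
      cand <- cand[ped$sex[match(cand, ped$id)] == "M"]
      fdate <- as.Date(paste0(year, "-12-20")) + sample.int(5L, 1L)
      cand <- cand[(as.numeric(fdate - ped$birth[match(cand, ped$id)]) /
        365.25) >= 4]
      donors <- unique(open$harem)
      donors <- donors[vapply(donors, function(h)
        sum(open$harem == h & open$role == "adult_female") >= 4, logical(1L))]
      if (length(cand) && length(donors)) {
        new_harem_no <- new_harem_no + 1L
        nh <- sprintf("N%02d", new_harem_no)
        s <- sample(cand, 1L)
        donor <- if (length(donors) == 1L) donors else sample(donors, 1L)
        fs <- open$id[open$harem == donor & open$role == "adult_female"]
        take <- sample(fs, sample(2:3, 1L))
        open_rec(s, nh, fdate, "harem_stallion")
        log_event(fdate, s, "new_harem", to = nh, role = "harem_stallion")
        for (f in take) {
          move(f, nh, fdate, "adult_female")
          log_event(fdate, f, "transfer", from = donor, to = nh,
            role = "adult_female")
        }
      }
    }
  }
  records <- rbind(
    if (!is.null(closed)) closed else NULL,
    if (!is.null(open)) cbind(open, end = as.Date(NA)) else NULL
  )
  records <- records[, c("id", "harem", "start", "end", "role")]
  list(
    pedigree = Pedigree(ped),
    membership = MembershipHistory(records),
    events = events[order(events$date), ],
    planted = list()
  )
}
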