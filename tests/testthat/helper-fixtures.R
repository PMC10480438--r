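# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# TrajectorySet from a named list of per-id (x, y) matrices / data.frames
makeTS <- function(tracks, frame_rate = 12.5, session_id = "S1",
                   status = NULL) {
  pos <- do.call(rbind, lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    data.frame(id = id, frame = seq_len(nrow(tr)) - 1L,
      x = tr[, 1L], y = tr[, 2L])
  }))
  TrajectorySet(pos, session_id = session_id, frame_rate = frame_rate,
    status = status)
}

# straight-line track
lineTrack <- function(n, x0 = 0, y0 = 0, vx = 1, vy = 0, fr = 12.5) {
  t <- (seq_len(n) - 1L) / fr
  cbind(x0 + vx * t, y0 + vy * t)
}

# meandering track (so headings vary over time and delay maxima are unique)
windingTrack <- function(n, seed = 1, speed = 0.85, fr = 12.5) {
  set.seed(seed)
  th <- cumsum(rnorm(n, 0, 0.05))
  cbind(cumsum(cos(th)) * speed / fr, cumsum(sin(th)) * speed / fr)
}

# random symmetric distance matrix with unique off-diagonal entries
randDistMatrix <- function(n, seed, lo = 1, hi = 100) {
  set.seed(seed)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- runif(n * (n - 1) / 2, lo, hi)
  M <- M + t(M)
  dimnames(M) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  M
}

# random pedigree: founders without parents, later generations with
# randomly known/unknown parents
randPedigree <- function(n = 50, seed = 1) {
  set.seed(seed)
  n_founders <- max(6L, round(n / 4))
  ids <- sprintf("X%03d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  birth <- as.Date("1998-01-01") + sort(sample.int(7000L, n))
  mother <- rep(NA_character_, n)
  father <- rep(NA_character_, n)
  for (k in (n_founders + 1L):n) {
    fem <- which(sex[1:(k - 1L)] == "F" & birth[1:(k - 1L)] < birth[k] - 700)
    mal <- which(sex[1:(k - 1L)] == "M" & birth[1:(k - 1L)] < birth[k] - 700)
    if (length(fem) && runif(1) < 0.85) mother[k] <- ids[sample(fem, 1L)]
    if (length(mal) && runif(1) < 0.7) father[k] <- ids[sample(mal, 1L)]
  }
  Pedigree(data.frame(id = ids, sex = sex, birth = birth,
    death = as.Date(NA), mother = mother, father = father,
    stringsAsFactors = FALSE))
}

# random membership history: individuals hop between harems on random dates
randMembership <- function(ids, harems = c("A", "B", "C"), seed = 1,
                           from = as.Date("2010-01-01"), years = 6) {
  set.seed(seed)
  rec <- NULL
  for (id in ids) {
    k <- sample(1:4, 1L)
    cuts <- sort(sample.int(365L * years, k - 1L))
    bounds <- c(0L, cuts, 365L * years)
    for (s in seq_len(k)) {
      rec <- rbind(rec, data.frame(
        id = id, harem = sample(harems, 1L),
        start = from + bounds[s], end = from + bounds[s + 1L],
        role = "adult_female", stringsAsFactors = FALSE
      ))
    }
  }
  MembershipHistory(rec)
}

smallHerdConfig <- function(...) {
  herdConfig(n_harems = 4L, n_individuals = 20L, n_bachelors = 4L,
    n_sessions = 2L, duration = 40, ...)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
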