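# Independent brute-force oracles. These deliberately re-derive every
# quantity with the dumbest possible algorithm (explicit loops, day scans,
# exhaustive enumeration) and never call the code paths they check.

# delayed directional correlation by triple loop (dyads x delays x frames)
oracle_dircorr <- function(hx, hy, frame_rate, tau_max = 16, tau_step = 1L,
                           min_overlap = 25L) {
  n <- ncol(hx)
  nf <- nrow(hx)
  kmax <- as.integer(round(tau_max * frame_rate))
  taus <- seq(-kmax, kmax, by = tau_step)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cv <- rep(NA_real_, length(taus))
      for (ti in seq_along(taus)) {
        tau <- taus[ti]
        s <- 0
        cnt <- 0L
        for (t in seq_len(nf)) {
          t2 <- t + tau
          if (t2 < 1L || t2 > nf) next
          a1 <- hx[t, i]
          b1 <- hx[t2, j]
          if (is.na(a1) || is.na(b1)) next
          s <- s + a1 * b1 + hy[t, i] * hy[t2, j]
          cnt <- cnt + 1L
        }
        if (cnt >= min_overlap) cv[ti] <- s / cnt
      }
      if (all(is.na(cv))) {
        c5 <- NA_real_
        bd <- NA_real_
      } else {
        best <- max(cv, na.rm = TRUE)
        cand <- which(!is.na(cv) & cv == best)
        cand <- cand[order(abs(taus[cand]), taus[cand])][1L]
        c5 <- best
        bd <- taus[cand] / frame_rate
        if (c5 < 0) {
          c5 <- NA_real_
          bd <- NA_real_
        }
      }
      out <- rbind(out, data.frame(i = i, j = j, c = c5, delay = bd))
    }
  }
  out
}

# breadth-first shortest path lengths from node `a` on a logical adjacency
oracle_bfs <- function(adj, a) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[a] <- 0
  queue <- a
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in which(adj[v, ])) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    d <- oracle_bfs(adj, v)
    reach <- is.finite(d) & d > 0
    if (!any(reach)) 0 else sum(reach) / sum(d[reach])
  }, numeric(1L))
}

oracle_connected <- function(adj) {
  all(is.finite(oracle_bfs(adj, 1L)))
}

# smallest threshold (scanning observed values) with a connected graph
oracle_critical_threshold <- function(gaps) {
  if (nrow(gaps) <= 1L) return(0)
  vals <- sort(unique(gaps[upper.tri(gaps)]))
  for (v in vals) {
    adj <- !is.na(gaps) & gaps <= v
    diag(adj) <- FALSE
    if (oracle_connected(adj)) return(v)
  }
  Inf
}

# shared harem days by day-by-day scan over the window
oracle_shared_days <- function(records, a, b, window) {
  days <- seq(as.Date(window[1L]), as.Date(window[2L]) - 1L, by = "day")
  assign_at <- function(id) {
    r <- records[records$id == id, , drop = FALSE]
    out <- rep(NA_character_, length(days))
    for (k in seq_len(nrow(r))) {
      e <- if (is.na(r$end[k])) as.Date("9999-01-01") else r$end[k]
      out[days >= r$start[k] & days < e] <- r$harem[k]
    }
    out
  }
  ha <- assign_at(a)
  hb <- assign_at(b)
  sum(!is.na(ha) & !is.na(hb) & ha == hb)
}

# kinship by explicit parent lookups
oracle_kinship <- function(ped_df, a, b) {
  row <- function(id) ped_df[ped_df$id == id, ]
  ra <- row(a)
  rb <- row(b)
  if ((!is.na(rb$mother) && rb$mother == a && rb$sex == "F") ||
    (!is.na(ra$mother) && ra$mother == b && ra$sex == "F")) {
    return("parent_offspring")
  }
  sm <- !is.na(ra$mother) && !is.na(rb$mother) && ra$mother == rb$mother
  sf <- !is.na(ra$father) && !is.na(rb$father) && ra$father == rb$father
  if (sm && sf) return("full_sibling")
  if (sm) return("maternal_half_sibling")
  if (sf) return("paternal_half_sibling")
  "distant"
}

# exact two-sample permutation p by enumerating all splits
oracle_two_sample_exact <- function(x, y, side = "greater") {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- mean(x) - mean(y)
  idx <- utils::combn(length(pooled), n1)
  stats <- apply(idx, 2L, function(k) {
    mean(pooled[k]) - mean(pooled[-k])
  })
  if (side == "greater") mean(stats >= obs) else mean(stats <= obs)
}

# exact paired permutation p by enumerating all sign patterns
oracle_paired_exact <- function(x, y, side = "greater") {
  d <- x - y
  obs <- mean(d)
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- signs %*% d / n
  if (side == "greater") mean(stats >= obs) else mean(stats <= obs)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (rest in all_perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
  }
  out
}

# exact correlation permutation p by enumerating all orderings of y
oracle_corr_exact <- function(x, y, side = "greater") {
  obs <- cor(x, y)
  stats <- vapply(all_perms(y), function(p) cor(x, p), numeric(1L))
  if (side == "greater") mean(stats >= obs) else mean(stats <= obs)
}

# assignment of an individual at a date, replayed from the event log
oracle_assignment_from_events <- function(events, id, date) {
  ev <- events[events$id == id & events$date <= date, , drop = FALSE]
  ev <- ev[order(ev$date), , drop = FALSE]
  cur <- NA_character_
  for (k in seq_len(nrow(ev))) {
    cur <- switch(ev$type[k],
      founding = ,
      birth = ,
      natal_dispersal = ,
      transfer = ,
      takeover_in = ,
      new_harem = if (is.na(ev$to[k])) NA_character_ else ev$to[k],
      takeover_out = ,
      death = NA_character_,
      cur
    )
  }
  cur
}
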