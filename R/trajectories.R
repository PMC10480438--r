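## Trajectory ingestion, smoothing and the two dyadic movement variables:
## pairwise distance (d_5min) and delayed directional-correlation movement
## similarity (C_5min), per session and averaged over sessions.

#' Construct a TrajectorySet
#'
#' @param positions data.frame with columns `id`, `frame`, `x`, `y` and
#'   optionally `time` (filled as `frame / frame_rate` when absent).
#' @param session_id session label.
#' @param frame_rate positions per second; the study regime is 12.5.
#' @param status named character vector (`"identified"` /
#'   `"unidentified_bachelor"`) per id; defaults to all identified.
#' @param duration session length in seconds; derived from the frame span
#'   when omitted.
#' @return A [TrajectorySet-class] object.
#' @export
TrajectorySet <- function(positions, session_id = "S1", frame_rate = 12.5,
                          status = NULL, duration = NULL) {
  positions <- as.data.frame(positions)
  positions$frame <- as.integer(positions$frame)
  positions$id <- as.character(positions$id)
  if (is.null(positions$time)) positions$time <- positions$frame / frame_rate
  if (is.null(status)) {
    status <- setNames(
      rep("identified", length(unique(positions$id))),
      unique(positions$id)
    )
  }
  if (is.null(duration)) {
    duration <- (max(positions$frame) - min(positions$frame) + 1L) / frame_rate
  }
  positions <- positions[order(positions$id, positions$frame,
    method = "radix"), , drop = FALSE]
  rownames(positions) <- NULL
  new("TrajectorySet",
    session_id = as.character(session_id), frame_rate = frame_rate,
    duration = duration,
    positions = positions[, c("id", "frame", "time", "x", "y")],
    status = status
  )
}

#' Read trajectories from the per-frame coordinate CSV
#'
#' Expects columns `session`, `frame` (or `time_s`), `individual_id`, `x_m`,
#' `y_m` and optionally `status`. Rows with non-finite coordinates are
#' dropped with a warning giving the count; duplicated `(id, frame)` rows
#' are a validation error.
#'
#' @param path CSV file path.
#' @param frame_rate positions per second (default 12.5).
#' @return A [TrajectorySet-class], or a named list of them if the file
#'   contains several sessions.
#' @export
readTrajectories <- function(path, frame_rate = 12.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "x_m", "y_m")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("malformed trajectory file ", path, ": missing column(s) ",
      paste(miss, collapse = ", "))
  }
  if (is.null(d$frame)) {
    if (is.null(d$time_s)) stop("need a 'frame' or 'time_s' column")
    d$frame <- as.integer(round(d$time_s * frame_rate))
  }
  if (is.null(d$session)) d$session <- "S1"
  bad <- !is.finite(d$x_m) | !is.finite(d$y_m)
  if (any(bad)) {
    warning("dropped ", sum(bad), " row(s) with non-finite coordinates")
    d <- d[!bad, , drop = FALSE]
  }
  one <- function(ds) {
    dup <- duplicated(ds[, c("individual_id", "frame")])
    if (any(dup)) {
      stop("duplicated (id, frame) rows, first at line ",
        which(dup)[1L] + 1L, " of session ", ds$session[1L])
    }
    st <- if (!is.null(ds$status)) {
      s <- ds$status[!duplicated(ds$individual_id)]
      setNames(s, ds$individual_id[!duplicated(ds$individual_id)])
    } else NULL
    TrajectorySet(
      data.frame(id = ds$individual_id, frame = ds$frame, x = ds$x_m,
        y = ds$y_m),
      session_id = ds$session[1L], frame_rate = frame_rate, status = st
    )
  }
  parts <- split(d, d$session)
  out <- lapply(parts, one)
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a TrajectorySet to the trajectory CSV dialect
#'
#' @param x a [TrajectorySet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(x, path) {
  p <- trackPositions(x)
  st <- trackStatus(x)
  out <- data.frame(
    session = sessionId(x), frame = p$frame, time_s = p$time,
    individual_id = p$id, x_m = p$x, y_m = p$y, status = unname(st[p$id])
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

## positions as frames x individuals matrices on the common frame grid
.posMatrices <- function(ts) {
  p <- ts@positions
  ids <- sort(unique(p$id))
  fr <- seq(min(p$frame), max(p$frame))
  X <- matrix(NA_real_, length(fr), length(ids), dimnames = list(NULL, ids))
  Y <- X
  ri <- p$frame - fr[1L] + 1L
  ci <- match(p$id, ids)
  X[cbind(ri, ci)] <- p$x
  Y[cbind(ri, ci)] <- p$y
  list(ids = ids, frames = as.integer(fr), time = fr / ts@frame_rate,
    x = X, y = Y)
}

## mask-renormalised Gaussian convolution of a series with gaps (NA);
## kernel truncated at 4 sigma. Returns values at the original index grid.
.gaussSmooth1 <- function(v, half, w) {
  mask <- as.numeric(!is.na(v))
  v0 <- ifelse(is.na(v), 0, v)
  num <- convolve(v0, w, type = "open")
  den <- convolve(mask, w, type = "open")
  n <- length(v)
  num <- num[(half + 1L):(half + n)]
  den <- den[(half + 1L):(half + n)]
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  out[is.na(v)] <- NA_real_ # keep the original gap pattern
  out
}

#' Gaussian smoothing of trajectories
#'
#' Convolves x and y independently with a truncated Gaussian kernel
#' (standard deviation `sigma` seconds, truncated at 4 sigma and
#' renormalised over the available mask, so constants are preserved also at
#' the edges and across gaps). Output frames and times are identical to the
#' input's. Individuals with fewer frames than the kernel support are
#' returned unsmoothed with a warning.
#'
#' @param ts a [TrajectorySet-class].
#' @param sigma kernel standard deviation in seconds (default 1.2).
#' @return A smoothed [TrajectorySet-class].
#' @export
gaussianSmooth <- function(ts, sigma = 1.2) {
  stopifnot(is(ts, "TrajectorySet"), sigma > 0)
  m <- .posMatrices(ts)
  half <- as.integer(ceiling(4 * sigma * ts@frame_rate))
  w <- dnorm((-half:half) / ts@frame_rate, sd = sigma)
  w <- w / sum(w)
  support <- 2L * half + 1L
  p <- ts@positions
  short <- character()
  for (j in seq_along(m$ids)) {
    v <- m$x[, j]
    nobs <- sum(!is.na(v))
    if (nobs < support) {
      short <- c(short, m$ids[j])
      next
    }
    m$x[, j] <- .gaussSmooth1(m$x[, j], half, w)
    m$y[, j] <- .gaussSmooth1(m$y[, j], half, w)
  }
  if (length(short)) {
    warning("individual(s) with fewer frames than the kernel support ",
      "returned unsmoothed: ", paste(short, collapse = ", "))
  }
  ri <- p$frame - m$frames[1L] + 1L
  ci <- match(p$id, m$ids)
  p$x <- m$x[cbind(ri, ci)]
  p$y <- m$y[cbind(ri, ci)]
  initialize(ts, positions = p)
}

#' Unit headings and speeds from smoothed positions
#'
#' Velocity is estimated by central finite differences on the frame grid;
#' the heading is the unit velocity vector wherever the speed is at least
#' `min_speed`, and flagged invalid otherwise (direction is undefined for a
#' near-stationary animal). Frames lacking either neighbour are invalid.
#'
#' @param ts a smoothed [TrajectorySet-class].
#' @param min_speed minimum speed in m/s for a defined heading
#'   (default 0.05; herd travel speed is around 0.85 m/s).
#' @return A [HeadingSeries-class].
#' @export
computeHeadings <- function(ts, min_speed = 0.05) {
  stopifnot(is(ts, "TrajectorySet"), min_speed >= 0)
  m <- .posMatrices(ts)
  nf <- nrow(m$x)
  vx <- matrix(NA_real_, nf, ncol(m$x), dimnames = dimnames(m$x))
  vy <- vx
  if (nf >= 3L) {
    dt2 <- 2 / ts@frame_rate
    vx[2:(nf - 1L), ] <- (m$x[3:nf, ] - m$x[1:(nf - 2L), ]) / dt2
    vy[2:(nf - 1L), ] <- (m$y[3:nf, ] - m$y[1:(nf - 2L), ]) / dt2
  }
  speed <- sqrt(vx^2 + vy^2)
  ok <- !is.na(speed) & speed >= min_speed
  hx <- ifelse(ok, vx / speed, NA_real_)
  hy <- ifelse(ok, vy / speed, NA_real_)
  new("HeadingSeries",
    ids = m$ids, frames = m$frames, time = m$time,
    hx = hx, hy = hy, speed = speed, frame_rate = ts@frame_rate
  )
}

#' Session-level pairwise distance
#'
#' For every unordered dyad, the mean Euclidean distance (metres) over the
#' frames where both individuals have positions. Dyads with no overlapping
#' frames are absent from the result.
#'
#' @param ts a [TrajectorySet-class] with at least two individuals.
#' @return data.frame with columns `session`, `id_a`, `id_b` (sorted so
#'   `id_a < id_b`), `d_5min` and `n_overlap`.
#' @export
pairwiseDistance <- function(ts) {
  stopifnot(is(ts, "TrajectorySet"))
  m <- .posMatrices(ts)
  if (length(m$ids) < 2L) stop("need at least 2 individuals")
  r <- .pair_mean_dist(m$x, m$y)
  out <- data.frame(
    session = ts@session_id,
    id_a = m$ids[r$i], id_b = m$ids[r$j],
    d_5min = r$d, n_overlap = r$n, stringsAsFactors = FALSE
  )
  out <- out[out$n_overlap > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Delayed directional correlation (movement similarity)
#'
#' For each dyad (i, j) the correlation at delay tau is the mean over valid
#' overlapping frames of the dot product of i's heading at t and j's heading
#' at t + tau. `c_5min` is the maximum over the delay grid
#' `[-tau_max, tau_max]` (step `tau_step` frames) and `best_delay_s` its
#' argmax; ties go to the smallest absolute delay, negative before positive.
#' Positive delay means j's heading is compared at a later time, i.e. j
#' follows i. Dyads whose maximum is negative, and dyads where no delay has
#' at least `min_overlap` valid overlapping frames, have `c_5min` absent
#' (NA).
#'
#' @param h a [HeadingSeries-class].
#' @param tau_max maximum delay magnitude in seconds (default 16); must be a
#'   multiple of the frame interval.
#' @param tau_step delay grid step in frames (default 1, i.e. 0.08 s at
#'   12.5 fps).
#' @param min_overlap minimum number of valid overlapping frames for a delay
#'   to compete (default 25, i.e. 2 s).
#' @return data.frame with columns `session`-free dyad fields `id_a`,
#'   `id_b`, `c_5min`, `best_delay_s`, `n_overlap`.
#' @export
directionalCorrelation <- function(h, tau_max = 16, tau_step = 1L,
                                   min_overlap = 25L) {
  stopifnot(is(h, "HeadingSeries"))
  kmax <- tau_max * h@frame_rate
  if (abs(kmax - round(kmax)) > 1e-9) {
    stop("tau_max must be a multiple of the frame interval")
  }
  kmax <- as.integer(round(kmax))
  taus <- seq(-kmax, kmax, by = as.integer(tau_step))
  taus <- taus[order(abs(taus), taus)] # preference order for tie-breaking
  r <- .dir_corr(h@hx, h@hy, taus, as.integer(min_overlap))
  c5 <- r$c
  bd <- r$tau / h@frame_rate
  neg <- r$has & !is.na(c5) & c5 < 0 # omission of negative maxima
  c5[neg] <- NA_real_
  bd[neg | !r$has] <- NA_real_
  data.frame(
    id_a = h@ids[r$i], id_b = h@ids[r$j],
    c_5min = c5, best_delay_s = bd, n_overlap = r$n0,
    stringsAsFactors = FALSE
  )
}

#' Session pair metrics: distance and movement similarity in one table
#'
#' Convenience wrapper: smooths the session, computes headings, and returns
#' the merged dyadic table of `d_5min`, `c_5min`, `best_delay_s`. Distances
#' are computed on the smoothed positions.
#'
#' @inheritParams gaussianSmooth
#' @inheritParams computeHeadings
#' @inheritParams directionalCorrelation
#' @param compute_c compute the directional correlation (set `FALSE` to get
#'   distances only, which is much cheaper on large sessions).
#' @return data.frame `session`, `id_a`, `id_b`, `d_5min`, `c_5min`,
#'   `best_delay_s`, `n_overlap`.
#' @export
sessionPairMetrics <- function(ts, sigma = 1.2, min_speed = 0.05,
                               tau_max = 16, tau_step = 1L, min_overlap = 25L,
                               compute_c = TRUE) {
  sm <- gaussianSmooth(ts, sigma = sigma)
  d <- pairwiseDistance(sm)
  if (!compute_c) {
    d$c_5min <- NA_real_
    d$best_delay_s <- NA_real_
    return(d[, c("session", "id_a", "id_b", "d_5min", "c_5min",
      "best_delay_s", "n_overlap")])
  }
  h <- computeHeadings(sm, min_speed = min_speed)
  cc <- directionalCorrelation(h, tau_max = tau_max, tau_step = tau_step,
    min_overlap = min_overlap)
  out <- merge(d, cc[, c("id_a", "id_b", "c_5min", "best_delay_s")],
    by = c("id_a", "id_b"), all.x = TRUE)
  out <- out[order(out$id_a, out$id_b),
    c("session", "id_a", "id_b", "d_5min", "c_5min", "best_delay_s",
      "n_overlap")]
  rownames(out) <- NULL
  out
}

#' Average dyadic metrics over sessions
#'
#' Unweighted means over the sessions where the dyad is present: `d_bar`
#' over all sessions with a distance, `c_bar` over sessions with a
#' non-omitted similarity. Dyads involving unidentified bachelors are
#' excluded, since bachelor identity cannot be matched across days.
#'
#' @param sessions list of session pair-metric data.frames (from
#'   [sessionPairMetrics()] or [pairwiseDistance()]).
#' @param bachelor_ids ids to exclude (unidentified bachelors).
#' @return data.frame `id_a`, `id_b`, `d_bar`, `c_bar`, `n_sessions`
#'   (sessions contributing to `d_bar`), `n_sessions_c`.
#' @export
averageSessions <- function(sessions, bachelor_ids = character()) {
  if (length(sessions) == 0L) stop("empty session list")
  all <- do.call(rbind, lapply(sessions, function(s) {
    if (is.null(s$c_5min)) s$c_5min <- NA_real_
    s[, c("id_a", "id_b", "d_5min", "c_5min")]
  }))
  keep <- !(all$id_a %in% bachelor_ids | all$id_b %in% bachelor_ids)
  all <- all[keep, , drop = FALSE]
  if (nrow(all) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
      d_bar = numeric(), c_bar = numeric(), n_sessions = integer(),
      n_sessions_c = integer()))
  }
  key <- paste(all$id_a, all$id_b, sep = "\r")
  d_bar <- tapply(all$d_5min, key, mean)
  n_s <- tapply(all$d_5min, key, length)
  c_bar <- tapply(all$c_5min, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  n_c <- tapply(all$c_5min, key, function(v) sum(!is.na(v)))
  ks <- strsplit(names(d_bar), "\r", fixed = TRUE)
  out <- data.frame(
    id_a = vapply(ks, `[`, "", 1L), id_b = vapply(ks, `[`, "", 2L),
    d_bar = as.numeric(d_bar), c_bar = as.numeric(c_bar),
    n_sessions = as.integer(n_s), n_sessions_c = as.integer(n_c),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

#' Write session or averaged pair metrics to CSV
#'
#' @param metrics a pair-metrics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePairMetrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
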