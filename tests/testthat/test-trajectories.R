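test_that("trajectory CSV ingest validates, drops bad rows, keeps good ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(
    session = "S1", frame = rep(0:9, 2),
    individual_id = rep(c("a", "b"), each = 10),
    x_m = rnorm(20), y_m = rnorm(20), status = "identified"
  )
  write.csv(d, f, row.names = FALSE)
  ts <- readTrajectories(f)
  expect_s4_class(ts, "TrajectorySet")
  expect_setequal(trackIds(ts), c("a", "b"))
  expect_equal(nrow(trackPositions(ts)), 20L)

  d2 <- d
  d2$x_m[3] <- NaN
  write.csv(d2, f, row.names = FALSE)
  expect_warning(ts2 <- readTrajectories(f), "non-finite")
  expect_equal(nrow(trackPositions(ts2)), 19L)

  d3 <- rbind(d, d[1, ])
  write.csv(d3, f, row.names = FALSE)
  expect_error(readTrajectories(f), "duplicated")

  write.csv(d[, -2][, -2], f, row.names = FALSE)
  expect_error(readTrajectories(f), "missing column")
})

test_that("trajectory CSV writer round-trips", {
  ts <- makeTS(list(a = lineTrack(30), b = lineTrack(30, y0 = 5)),
    status = c(a = "identified", b = "unidentified_bachelor"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrajectories(ts, f)
  back <- readTrajectories(f)
  expect_equal(trackPositions(back), trackPositions(ts))
  expect_equal(trackStatus(back), trackStatus(ts))
})

test_that("Gaussian smoothing preserves constants and straight lines", {
  n <- 200L
  const <- makeTS(list(a = cbind(rep(3, n), rep(-7, n)),
    b = lineTrack(n, vx = 0.9)))
  sm <- gaussianSmooth(const, sigma = 1.2)
  p <- trackPositions(sm)
  expect_equal(p$x[p$id == "a"], rep(3, n), tolerance = 1e-10)
  expect_equal(p$y[p$id == "a"], rep(-7, n), tolerance = 1e-10)
  ## straight line: interior frames unchanged, edges within kernel half-width
  half <- ceiling(4 * 1.2 * 12.5)
  lx <- lineTrack(n, vx = 0.9)[, 1L]
  smx <- p$x[p$id == "b"]
  interior <- (half + 1L):(n - half)
  expect_equal(smx[interior], lx[interior], tolerance = 1e-9)
})

test_that("Gaussian smoothing attenuates a sinusoid by the analytic factor", {
  fr <- 12.5
  n <- 4000L
  f0 <- 0.1
  sigma <- 1.2
  t <- (seq_len(n) - 1L) / fr
  ts <- makeTS(list(a = cbind(sin(2 * pi * f0 * t), rep(0, n))),
    frame_rate = fr)
  sm <- gaussianSmooth(ts, sigma = sigma)
  x <- trackPositions(sm)$x
  half <- ceiling(4 * sigma * fr)
  interior <- (half + 1L):(n - half)
  ## amplitude by projection onto the sine basis; the truncated discrete
  ## kernel deviates from the continuous transfer function by ~1e-3
  amp <- 2 * mean(x[interior] * sin(2 * pi * f0 * t[interior]))
  expect_equal(amp, exp(-2 * pi^2 * f0^2 * sigma^2), tolerance = 5e-3)
})

test_that("smoothing leaves short tracks untouched, with a warning", {
  ts <- makeTS(list(a = lineTrack(10), b = lineTrack(300)))
  expect_warning(sm <- gaussianSmooth(ts), "fewer frames")
  pa <- trackPositions(sm)
  expect_equal(pa$x[pa$id == "a"], lineTrack(10)[, 1L])
})

test_that("headings: straight motion, stationary track, circular closed form", {
  fr <- 12.5
  n <- 100L
  ts <- makeTS(list(a = lineTrack(n, vx = 1), b = cbind(rep(1, n), rep(2, n))),
    frame_rate = fr)
  h <- computeHeadings(ts, min_speed = 0.05)
  ia <- match("a", h@ids)
  ib <- match("b", h@ids)
  expect_equal(unname(h@hx[2:(n - 1L), ia]), rep(1, n - 2L), tolerance = 1e-12)
  expect_equal(unname(h@hy[2:(n - 1L), ia]), rep(0, n - 2L), tolerance = 1e-12)
  expect_true(all(is.na(h@hx[, ib]))) # speed 0 < min_speed

  ## circular motion: heading tangent; dot product over lag = cos(omega * dt)
  R <- 10
  omega <- 0.3
  tt <- (seq_len(400L) - 1L) / fr
  circ <- makeTS(list(c = cbind(R * cos(omega * tt), R * sin(omega * tt))),
    frame_rate = fr)
  hc <- computeHeadings(circ, min_speed = 0.05)
  lag <- 25L
  v <- 2:(400L - 1L)
  v2 <- v[v + lag <= 399L]
  dots <- hc@hx[v2, 1L] * hc@hx[v2 + lag, 1L] +
    hc@hy[v2, 1L] * hc@hy[v2 + lag, 1L]
  expect_equal(unname(dots), rep(cos(omega * lag / fr), length(v2)),
    tolerance = 1e-8)
})

test_that("pairwise distance: constants, parallel motion, partial overlap", {
  n <- 50L
  ts <- makeTS(list(
    a = cbind(rep(0, n), rep(0, n)),
    b = cbind(rep(3, n), rep(0, n))
  ))
  d <- pairwiseDistance(ts)
  expect_equal(d$d_5min, 3)
  expect_equal(d$n_overlap, n)

  ts2 <- makeTS(list(a = lineTrack(n, vx = 1), b = lineTrack(n, y0 = 5, vx = 1)))
  expect_equal(pairwiseDistance(ts2)$d_5min, 5, tolerance = 1e-12)

  ## partial overlap vs frame-by-frame recomputation
  set.seed(7)
  xa <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
  xb <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
  pos <- rbind(
    data.frame(id = "a", frame = 0:39, x = xa[, 1], y = xa[, 2]),
    data.frame(id = "b", frame = 20:59, x = xb[, 1], y = xb[, 2])
  )
  ts3 <- TrajectorySet(pos)
  d3 <- pairwiseDistance(ts3)
  common <- 21:40 # a frames 20..39 overlap b frames 20..39
  manual <- mean(sqrt((xa[common, 1] - xb[1:20, 1])^2 +
    (xa[common, 2] - xb[1:20, 2])^2))
  expect_equal(d3$d_5min, manual, tolerance = 1e-12)
  expect_equal(d3$n_overlap, 20L)
})

test_that("directional correlation: identity, shift recovery, omission rules", {
  fr <- 12.5
  n <- 1000L
  w <- windingTrack(n, seed = 3)
  ts <- makeTS(list(a = w, b = w), frame_rate = fr)
  h <- computeHeadings(ts, min_speed = 0)
  cc <- directionalCorrelation(h, tau_max = 4)
  expect_equal(cc$c_5min, 1, tolerance = 1e-12)
  expect_equal(cc$best_delay_s, 0)

  ## injected shift of +4 s recovered; verified against exhaustive scan
  k <- round(4 * fr)
  pos <- rbind(
    data.frame(id = "a", frame = 0:(n - 1), x = w[, 1], y = w[, 2]),
    data.frame(id = "b", frame = k:(n - 1), x = w[1:(n - k), 1],
      y = w[1:(n - k), 2])
  )
  h2 <- computeHeadings(TrajectorySet(pos, frame_rate = fr), min_speed = 0)
  cc2 <- directionalCorrelation(h2, tau_max = 8)
  expect_equal(cc2$best_delay_s, 4)
  expect_equal(cc2$c_5min, 1, tolerance = 1e-9)
  orc <- oracle_dircorr(h2@hx, h2@hy, fr, tau_max = 8)
  expect_equal(cc2$c_5min, orc$c, tolerance = 1e-12)
  expect_equal(cc2$best_delay_s, orc$delay)

  ## anti-aligned headings: maximum is negative -> omitted
  n2 <- 200L
  opp <- makeTS(list(a = lineTrack(n2, vx = 1),
    b = lineTrack(n2, x0 = 50, vx = -1)), frame_rate = fr)
  h3 <- computeHeadings(opp, min_speed = 0.05)
  cc3 <- directionalCorrelation(h3, tau_max = 2)
  expect_true(is.na(cc3$c_5min))
  expect_true(is.na(cc3$best_delay_s))
  expect_gt(cc3$n_overlap, 0)

  ## insufficient overlap -> absent
  cc4 <- directionalCorrelation(h3, tau_max = 2, min_overlap = 10000L)
  expect_true(is.na(cc4$c_5min))

  ## tau_max must sit on the frame grid
  expect_error(directionalCorrelation(h3, tau_max = 0.1), "multiple")
})

test_that("session averaging follows the stated rules", {
  s <- function(d, c) {
    data.frame(session = "S", id_a = "a", id_b = "b", d_5min = d, c_5min = c,
      best_delay_s = 0, n_overlap = 100L)
  }
  avg <- averageSessions(list(s(10, 0.9), s(20, NA), s(30, 0.7)))
  expect_equal(avg$d_bar, 20)
  expect_equal(avg$c_bar, 0.8)
  expect_equal(avg$n_sessions, 3L)
  expect_equal(avg$n_sessions_c, 2L)

  ## bachelor dyads excluded
  two <- rbind(s(10, 0.9), data.frame(session = "S", id_a = "a", id_b = "z",
    d_5min = 5, c_5min = 0.5, best_delay_s = 0, n_overlap = 100L))
  avg2 <- averageSessions(list(two), bachelor_ids = "z")
  expect_equal(nrow(avg2), 1L)
  expect_equal(avg2$id_b, "b")

  expect_error(averageSessions(list()), "empty")
})

test_that("dyad symmetry: metrics invariant to id order, delay negates", {
  fr <- 12.5
  n <- 600L
  w1 <- windingTrack(n, seed = 5)
  w2 <- windingTrack(n, seed = 6) + 10
  ## same physical tracks, identities swapped so the canonical dyad flips
  ts_ab <- makeTS(list(a = w1, b = w2), frame_rate = fr)
  ts_ba <- makeTS(list(b = w1, a = w2), frame_rate = fr)
  m1 <- sessionPairMetrics(ts_ab, min_speed = 0, tau_max = 4)
  m2 <- sessionPairMetrics(ts_ba, min_speed = 0, tau_max = 4)
  expect_equal(m1$d_5min, m2$d_5min, tolerance = 1e-12)
  expect_equal(m1$c_5min, m2$c_5min, tolerance = 1e-12)
  expect_equal(m1$best_delay_s, -m2$best_delay_s)
})

test_that("rigid translation leaves distances and correlations unchanged", {
  fr <- 12.5
  n <- 500L
  tracks <- list(a = windingTrack(n, 11), b = windingTrack(n, 12) + 5,
    c = windingTrack(n, 13) - 3)
  shifted <- lapply(tracks, function(m) sweep(m, 2L, c(-137.2, 64.1), "+"))
  m1 <- sessionPairMetrics(makeTS(tracks, frame_rate = fr), min_speed = 0,
    tau_max = 2)
  m2 <- sessionPairMetrics(makeTS(shifted, frame_rate = fr), min_speed = 0,
    tau_max = 2)
  expect_equal(m1$d_5min, m2$d_5min, tolerance = 1e-9)
  expect_equal(m1$c_5min, m2$c_5min, tolerance = 1e-9)
  expect_equal(m1$best_delay_s, m2$best_delay_s)
})

test_that("directional correlation equals the brute-force triple loop", {
  fr <- 12.5
  for (case in 1:5) {
    set.seed(100 + case)
    n_ind <- sample(3:5, 1L)
    nf <- sample(100:200, 1L)
    tracks <- setNames(
      lapply(seq_len(n_ind), function(k) windingTrack(nf, 200 + case * 10 + k)),
      paste0("i", seq_len(n_ind))
    )
    h <- computeHeadings(makeTS(tracks, frame_rate = fr), min_speed = 0)
    got <- directionalCorrelation(h, tau_max = 1.6, min_overlap = 10L)
    orc <- oracle_dircorr(h@hx, h@hy, fr, tau_max = 1.6, min_overlap = 10L)
    expect_equal(got$c_5min, orc$c, tolerance = 1e-12)
    expect_equal(got$best_delay_s, orc$delay)
  }
})
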