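## Synthetic multilevel herd generator with full ground truth: nested
## mean-reverting walks (individual around family, family around harem
## anchor, anchor around the moving herd centroid) reproduce the bimodal
## pairwise-distance structure and coherent headings the analysis assumes.

#' Herd simulation configuration
#'
#' Defaults follow the observed regime: 31 harems totalling 238 identified
#' individuals plus 40 unidentified bachelor tracks, herd travel speed
#' 0.85 m/s, five 320-s sessions at 12.5 positions/s. The three cohesion
#' scales must be strictly ordered (family < harem < herd); they are free
#' generator constants chosen to give a clearly bimodal distance
#' distribution.
#'
#' @param n_harems number of harems (default 31).
#' @param n_individuals total identified harem-living individuals
#'   (default 238).
#' @param n_bachelors unidentified bachelor tracks (default 40).
#' @param intra_family_scale typical offspring-mother distance, m (default 5).
#' @param intra_harem_scale typical member-member distance within a harem,
#'   m (default 15).
#' @param inter_harem_scale typical nearest-harem anchor spacing, m
#'   (default 120).
#' @param herd_speed herd travel speed, m/s (default 0.85).
#' @param frame_rate positions per second (default 12.5).
#' @param duration session length, s (default 320).
#' @param n_sessions number of sessions (default 5).
#' @param offspring_prob probability that a non-stallion harem slot is a
#'   pre-dispersal offspring attached to an adult female (default 0.45).
#' @return validated configuration list (class `herd_config`).
#' @export
herdConfig <- function(n_harems = 31L, n_individuals = 238L,
                       n_bachelors = 40L, intra_family_scale = 5,
                       intra_harem_scale = 15, inter_harem_scale = 120,
                       herd_speed = 0.85, frame_rate = 12.5, duration = 320,
                       n_sessions = 5L, offspring_prob = 0.45) {
  cfg <- list(
    n_harems = as.integer(n_harems),
    n_individuals = as.integer(n_individuals),
    n_bachelors = as.integer(n_bachelors),
    intra_family_scale = intra_family_scale,
    intra_harem_scale = intra_harem_scale,
    inter_harem_scale = inter_harem_scale,
    herd_speed = herd_speed, frame_rate = frame_rate, duration = duration,
    n_sessions = as.integer(n_sessions), offspring_prob = offspring_prob
  )
  if (any(unlist(cfg[4:6]) <= 0)) stop("cohesion scales must be positive")
  ## equality of the harem and herd scales is allowed as a degenerate
  ## (unimodal) control; the family scale must stay strictly smallest
  if (!(cfg$intra_family_scale < cfg$intra_harem_scale &&
    cfg$intra_harem_scale <= cfg$inter_harem_scale)) {
    stop("cohesion scales must be ordered: ",
      "intra_family < intra_harem <= inter_harem")
  }
  if (cfg$n_individuals < 2L * cfg$n_harems) {
    stop("need at least 2 individuals per harem")
  }
  class(cfg) <- "herd_config"
  cfg
}

#' Herd layout: social structure and home offsets
#'
#' Draws the harem composition (stallion, adult females, their pre-dispersal
#' offspring) and places harem home offsets on a jittered grid with spacing
#' `inter_harem_scale`; bachelor tracks get peripheral home offsets beyond
#' the harem ring. The layout is the ground truth against which
#' movement-only classification is scored, and the object on which spatial
#' effects are planted.
#'
#' @param config a [herdConfig()].
#' @param seed RNG seed.
#' @return list (class `herd_layout`): `individuals` data.frame (`id`,
#'   `harem`, `role`, `mother`), `bachelors` ids, `harem_homes` (matrix,
#'   m), `bachelor_homes`, `member_offsets` (matrix: member home offset
#'   within harem), `config`, `planted` (manifest list).
#' @export
herdLayout <- function(config, seed = 1L) {
  stopifnot(inherits(config, "herd_config"))
  .withSeed(seed, {
    nh <- config$n_harems
    ## peripheral (straggler) harems are the last n_per; they are young and
    ## small (stallion + 1-2 females), the core harems share the rest
    n_per <- if (nh >= 10L) max(2L, round(0.13 * nh)) else 0L
    n_core <- nh - n_per
    ## harem sizes: stallion + 1 female guaranteed, rest multinomial
    sizes <- rep(2L, nh)
    if (n_per > 0L) {
      sizes[(n_core + 1L):nh] <- sizes[(n_core + 1L):nh] +
        sample(0:1, n_per, replace = TRUE)
    }
    extra <- config$n_individuals - sum(sizes)
    if (extra > 0L) {
      add <- table(factor(sample.int(n_core, extra, replace = TRUE),
        levels = seq_len(nh)))
      sizes <- sizes + as.integer(add)
    }
    rows <- list()
    for (h in seq_len(nh)) {
      hid <- sprintf("H%02d", h)
      ids <- sprintf("%s_I%02d", hid, seq_len(sizes[h]))
      role <- c("stallion", "female",
        rep(NA_character_, max(0L, sizes[h] - 2L)))
      mother <- rep(NA_character_, sizes[h])
      for (k in seq_len(sizes[h])[-(1:2)]) {
        females <- ids[which(role == "female")]
        if (runif(1) < config$offspring_prob && length(females)) {
          role[k] <- "offspring"
          mother[k] <- sample(females, 1L)
        } else {
          role[k] <- "female"
        }
      }
      rows[[h]] <- data.frame(id = ids, harem = hid, role = role,
        mother = mother, stringsAsFactors = FALSE)
    }
    individuals <- do.call(rbind, rows)
    ## harem homes: a dense core (uniform in a disk, pair-repaired so no two
    ## homes come closer than 0.75 x the inter-harem scale — harems keep
    ## exclusive space, which is what makes movement-only classification
    ## possible) plus ~20% peripheral harems attached at 1.3-1.6 x the scale.
    ## The peripheral stragglers set the critical network threshold while
    ## the core stays well connected, so the network is robust to modest
    ## threshold changes.
    g <- config$inter_harem_scale
    ## core: uniform in a disk, pair-repaired to a minimum separation of
    ## 0.75 g (exclusive space), redrawn until the core threshold graph is
    ## tight (MST max edge <= g) so the core never fragments at thresholds
    ## the stragglers set
    for (try in seq_len(25L)) {
      rr <- 0.42 * g * sqrt(n_core) * sqrt(runif(n_core))
      aa <- runif(n_core, 0, 2 * pi)
      harem_homes <- cbind(x = rr * cos(aa), y = rr * sin(aa))
      if (n_core >= 2L) {
        for (iter in seq_len(500L)) {
          D <- as.matrix(dist(harem_homes))
          diag(D) <- Inf
          if (min(D) >= 0.75 * g) break
          ij <- which(D == min(D), arr.ind = TRUE)[1L, ]
          u <- harem_homes[ij[2L], ] - harem_homes[ij[1L], ]
          nu <- sqrt(sum(u^2))
          u <- if (nu > 0) u / nu else c(1, 0)
          push <- (0.78 * g - nu) / 2
          harem_homes[ij[1L], ] <- harem_homes[ij[1L], ] - u * push
          harem_homes[ij[2L], ] <- harem_homes[ij[2L], ] + u * push
        }
      }
      if (n_core < 2L || .mstMaxEdge(as.matrix(dist(harem_homes))) <= g) break
    }
    if (n_per > 0L) {
      ## peripheral stragglers: radial spurs off the core hull at
      ## 1.15-1.55 x the scale, mutually separated by at least 1.8 x the
      ## scale so each isolates singly (never as a pair) when the network
      ## threshold drops below its attachment gap
      core_homes <- harem_homes
      placed <- NULL
      for (p in seq_len(n_per)) {
        for (try in seq_len(100L)) {
          ang <- runif(1, 0, 2 * pi)
          u <- c(cos(ang), sin(ang))
          hull <- core_homes[which.max(core_homes %*% u), ]
          pos <- hull + u * g * runif(1, 1.15, 1.55)
          ok <- is.null(placed) ||
            min(sqrt(rowSums(sweep(placed, 2L, pos)^2))) >= 1.8 * g
          if (ok) break
        }
        placed <- rbind(placed, pos)
      }
      harem_homes <- rbind(harem_homes, placed)
    }
    rownames(harem_homes) <- sprintf("H%02d", seq_len(nh))
    ## member home offsets within the harem
    n <- nrow(individuals)
    member_offsets <- matrix(rnorm(2L * n, 0, config$intra_harem_scale / 2),
      n, 2L, dimnames = list(individuals$id, c("x", "y")))
    off <- individuals$role == "offspring"
    ## offspring sit near their mother
    member_offsets[off, ] <- member_offsets[match(
      individuals$mother[off], individuals$id), , drop = FALSE] +
      matrix(rnorm(2L * sum(off), 0, config$intra_family_scale / 2),
        sum(off), 2L)
    ## bachelors on the periphery, grouped into a few loose bands
    nb <- config$n_bachelors
    bachelors <- if (nb > 0L) sprintf("B%02d", seq_len(nb)) else character()
    extent <- max(abs(harem_homes)) + g
    n_groups <- max(1L, round(nb / 15))
    gang <- sort(runif(n_groups, 0, 2 * pi))
    ang <- gang[1L + (seq_len(nb) %% n_groups)]
    bachelor_homes <- cbind(
      x = extent * cos(ang) + rnorm(nb, 0, config$intra_harem_scale),
      y = extent * sin(ang) + rnorm(nb, 0, config$intra_harem_scale)
    )
    if (nb > 0L) rownames(bachelor_homes) <- bachelors
    structure(list(
      individuals = individuals, bachelors = bachelors,
      harem_homes = harem_homes, bachelor_homes = bachelor_homes,
      member_offsets = member_offsets, config = config, planted = list()
    ), class = "herd_layout")
  })
}

## smooth planar mean-reverting wobble: a critically damped second-order
## process, so offsets have differentiable paths (headings stay meaningful).
## sd_pos: stationary positional sd per axis; sd_vel: stationary velocity sd.
.smoothWobble <- function(nf, dt, sd_pos, sd_vel) {
  if (sd_pos <= 0) return(matrix(0, nf, 2L))
  omega <- sd_vel / sd_pos
  damp <- 2 * omega
  sw <- sd_vel * sqrt(2 * damp)
  ## Euler discretisation pos' = vel, vel' = -omega^2 pos - damp vel + noise
  ## collapses to the AR(2) recursion
  ##   pos_t = a1 pos_{t-1} + a2 pos_{t-2} + dt * noise shock
  a1 <- 2 - damp * dt
  a2 <- -(1 - damp * dt + omega^2 * dt^2)
  one <- function() {
    pos0 <- rnorm(1L, 0, sd_pos)
    vel0 <- rnorm(1L, 0, sd_vel)
    e <- rnorm(nf, 0, sw * dt^1.5)
    as.numeric(stats::filter(e, c(a1, a2), method = "recursive",
      init = c(pos0, pos0 - dt * vel0)))
  }
  cbind(one(), one())
}

#' Simulate multilevel herd trajectories
#'
#' The herd centroid follows a smooth correlated random walk at
#' `herd_speed`; each harem anchor performs a smooth mean-reverting wobble
#' around its home offset from the centroid; each individual wobbles around
#' its harem anchor (offspring around their mother), and bachelors around
#' peripheral homes. Sessions are independent draws of all wobbles with the
#' same layout, so session-averaged distances concentrate around the layout
#' geometry.
#'
#' @param config a [herdConfig()].
#' @param seed RNG seed; session s uses `seed * 1000 + s` internally.
#' @param layout optional pre-built (possibly effect-planted)
#'   [herdLayout()]; defaults to `herdLayout(config, seed)`.
#' @param noise_scale multiplier on all wobble magnitudes (0 = rigid
#'   formation, useful as a degenerate control).
#' @return list: `sessions` (list of [TrajectorySet-class]), `truth` (list
#'   with `assignment` named id -> harem, `individuals`, `bachelors`,
#'   `layout`).
#' @export
simulateHerd <- function(config, seed = 1L, layout = NULL, noise_scale = 1) {
  stopifnot(inherits(config, "herd_config"))
  if (is.null(layout)) layout <- herdLayout(config, seed)
  ind <- layout$individuals
  nb <- length(layout$bachelors)
  dt <- 1 / config$frame_rate
  nf <- as.integer(round(config$duration * config$frame_rate))
  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    sessions[[s]] <- .withSeed(seed * 1000L + s, {
      ## herd centroid: slowly turning heading at constant speed
      theta <- cumsum(c(runif(1, 0, 2 * pi),
        rnorm(nf - 1L, 0, 0.25 * sqrt(dt))))
      cx <- cumsum(config$herd_speed * cos(theta) * dt)
      cy <- cumsum(config$herd_speed * sin(theta) * dt)
      ns <- noise_scale
      ## harem anchors: session-level re-jitter of the home + smooth wobble
      anchors <- lapply(seq_len(config$n_harems), function(h) {
        wob <- .smoothWobble(nf, dt, ns * 0.05 * config$inter_harem_scale,
          0.35 * ns + 1e-12)
        jit <- rnorm(2L, 0, ns * 0.05 * config$inter_harem_scale)
        cbind(cx + layout$harem_homes[h, 1L] + jit[1L] + wob[, 1L],
          cy + layout$harem_homes[h, 2L] + jit[2L] + wob[, 2L])
      })
      names(anchors) <- rownames(layout$harem_homes)
      ## members around anchors; offspring around their mother's path
      pos <- vector("list", nrow(ind) + nb)
      ord <- order(ind$role == "offspring") # mothers first
      for (k in ord) {
        wob <- .smoothWobble(nf, dt,
          ns * (if (ind$role[k] == "offspring")
            config$intra_family_scale / 2 else config$intra_harem_scale / 6),
          0.30 * ns + 1e-12)
        base <- if (ind$role[k] == "offspring") {
          pos[[match(ind$mother[k], ind$id)]]
        } else {
          a <- anchors[[ind$harem[k]]]
          cbind(a[, 1L] + layout$member_offsets[k, 1L],
            a[, 2L] + layout$member_offsets[k, 2L])
        }
        pos[[k]] <- cbind(base[, 1L] + wob[, 1L], base[, 2L] + wob[, 2L])
      }
      for (b in seq_len(nb)) {
        wob <- .smoothWobble(nf, dt, ns * config$intra_harem_scale / 3,
          0.30 * ns + 1e-12)
        pos[[nrow(ind) + b]] <- cbind(
          cx + layout$bachelor_homes[b, 1L] + wob[, 1L],
          cy + layout$bachelor_homes[b, 2L] + wob[, 2L])
      }
      ids <- c(ind$id, layout$bachelors)
      positions <- data.frame(
        id = rep(ids, each = nf),
        frame = rep.int(seq_len(nf) - 1L, length(ids)),
        x = unlist(lapply(pos, function(p) p[, 1L]), use.names = FALSE),
        y = unlist(lapply(pos, function(p) p[, 2L]), use.names = FALSE)
      )
      status <- setNames(c(rep("identified", nrow(ind)),
        rep("unidentified_bachelor", nb)), ids)
      TrajectorySet(positions, session_id = sprintf("S%d", s),
        frame_rate = config$frame_rate, status = status,
        duration = config$duration)
    })
  }
  truth <- list(
    assignment = setNames(ind$harem, ind$id),
    individuals = ind, bachelors = layout$bachelors, layout = layout
  )
  list(sessions = sessions, truth = truth)
}

#' Plant effects into a layout or simulated population
#'
#' Creates the alternative hypotheses the analysis tests, with a manifest of
#' the planted truth for power analysis. Supported effects:
#' \describe{
#'   \item{`sibling_stallion_proximity`}{on a `herd_layout`: multiplies the
#'     home separation of the given harem pairs by `factor` < 1 (both homes
#'     move towards their midpoint). `pairs` is a 2-column matrix/data.frame
#'     of harem ids.}
#'   \item{`future_coresidency`}{on a simulated population (list with a
#'     `membership` element): appends a shared post-observation membership
#'     interval for each given female pair. Arguments: `pairs` (2-column,
#'     ids), `start`, `days`, `harem_prefix`.}
#' }
#'
#' @param x a `herd_layout` or a `simulatePopulation()` result.
#' @param effect effect name.
#' @param ... effect arguments (see Details).
#' @return modified object; the manifest accumulates in `x$planted`.
#' @export
plantEffects <- function(x, effect, ...) {
  args <- list(...)
  if (effect == "sibling_stallion_proximity") {
    stopifnot(inherits(x, "herd_layout"))
    pairs <- as.matrix(args$pairs)
    factor <- args$factor
    if (is.null(factor)) stop("effect needs a 'factor' argument")
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]
      b <- pairs[r, 2L]
      mid <- (x$harem_homes[a, ] + x$harem_homes[b, ]) / 2
      x$harem_homes[a, ] <- mid + (x$harem_homes[a, ] - mid) * factor
      x$harem_homes[b, ] <- mid + (x$harem_homes[b, ] - mid) * factor
    }
    x$planted <- c(x$planted, list(list(
      effect = effect, pairs = pairs, factor = factor)))
    return(x)
  }
  if (effect == "future_coresidency") {
    stopifnot(is.list(x), !is.null(x$membership))
    pairs <- as.matrix(args$pairs)
    start <- as.Date(args$start)
    days <- if (is.null(args$days)) 365 else args$days
    prefix <- if (is.null(args$harem_prefix)) "HP" else args$harem_prefix
    rec <- membershipRecords(x$membership)
    add <- NULL
    for (r in seq_len(nrow(pairs))) {
      h <- sprintf("%s%02d", prefix, r)
      add <- rbind(add, data.frame(
        id = c(pairs[r, 1L], pairs[r, 2L]), harem = h,
        start = start, end = start + days, role = "adult_female",
        stringsAsFactors = FALSE
      ))
    }
    ## close any record that would overlap the planted interval
    endn <- ifelse(is.na(rec$end), Inf, as.numeric(rec$end))
    for (id in unique(add$id)) {
      k <- rec$id == id & as.numeric(rec$start) < as.numeric(start) &
        endn > as.numeric(start)
      rec$end[k] <- start
      k2 <- rec$id == id & as.numeric(rec$start) >= as.numeric(start) &
        as.numeric(rec$start) < as.numeric(start) + days
      rec <- rec[!k2, , drop = FALSE]
      endn <- ifelse(is.na(rec$end), Inf, as.numeric(rec$end))
    }
    x$membership <- MembershipHistory(rbind(rec, add))
    x$planted <- c(x$planted, list(list(
      effect = effect, pairs = pairs, start = start, days = days)))
    return(x)
  }
  stop("unknown effect: ", effect)
}

#' Demographic records matched to a herd layout
#'
#' Fabricates a pedigree and membership history consistent with the herd's
#' ground-truth structure, for end-to-end runs that join movement to
#' demography: every individual holds its truth harem over a window around
#' the observation date; planted stallion sibling pairs (shared founder
#' dam/sire), planted same-harem female sibling pairs, and planted
#' cross-harem female pairs with shared past membership provide known
#' kinship and familiarity signal.
#'
#' @param layout a [herdLayout()].
#' @param observation_date Date of the movement observations.
#' @param seed RNG seed.
#' @param sibling_stallion_pairs number of stallion full-sibling pairs to
#'   plant (default 3).
#' @param sibling_female_pairs number of same-harem adult-female sibling
#'   pairs to plant (default 4).
#' @param familiar_pairs number of cross-harem female pairs given a shared
#'   past harem (default 5; 400 shared days each).
#' @param tenure_days length of the current membership records before the
#'   observation date (default 700).
#' @return list: `pedigree`, `membership`, `observation_date`,
#'   `stallion_sibling_harem_pairs` (2-column matrix of harem ids),
#'   `planted` manifest.
#' @export
herdDemography <- function(layout, observation_date = as.Date("2018-08-17"),
                           seed = 1L, sibling_stallion_pairs = 3L,
                           sibling_female_pairs = 4L, familiar_pairs = 5L,
                           tenure_days = 700L) {
  stopifnot(inherits(layout, "herd_layout"))
  obs <- as.Date(observation_date)
  .withSeed(seed, {
    ind <- layout$individuals
    n <- nrow(ind)
    sex <- ifelse(ind$role == "stallion", "M",
      ifelse(ind$role == "female", "F", sample(c("F", "M"), n, TRUE)))
    age <- numeric(n)
    age[ind$role == "stallion"] <- runif(sum(ind$role == "stallion"), 6, 15)
    age[ind$role == "female"] <- runif(sum(ind$role == "female"), 3, 12)
    off <- which(ind$role == "offspring")
    for (k in off) {
      mother_age <- age[match(ind$mother[k], ind$id)]
      age[k] <- runif(1, 1, max(1.5, min(5, mother_age - 2)))
    }
    birth <- obs - round(age * 365.25)
    mother <- ind$mother
    father <- rep(NA_character_, n)
    ## offspring sired by the harem stallion
    stallion_of <- setNames(ind$id[ind$role == "stallion"],
      ind$harem[ind$role == "stallion"])
    father[off] <- unname(stallion_of[ind$harem[off]])
    ## founder generation carrying the planted sibling links
    founders <- NULL
    fno <- 0L
    new_founder <- function(sex) {
      fno <<- fno + 1L
      fid <- sprintf("FND%02d", fno)
      founders <<- rbind(founders, data.frame(id = fid, sex = sex,
        birth = obs - round(30 * 365.25), death = obs - round(8 * 365.25),
        mother = NA_character_, father = NA_character_,
        stringsAsFactors = FALSE))
      fid
    }
    stallions <- ind$id[ind$role == "stallion"]
    ns_pairs <- min(sibling_stallion_pairs, floor(length(stallions) / 2))
    st_pick <- sample(stallions, 2L * ns_pairs)
    st_pairs <- matrix(st_pick, ncol = 2L)
    for (r in seq_len(ns_pairs)) {
      dam <- new_founder("F")
      sire <- new_founder("M")
      idx <- match(st_pairs[r, ], ind$id)
      mother[idx] <- dam
      father[idx] <- sire
    }
    harem_of <- setNames(ind$harem, ind$id)
    stallion_sibling_harem_pairs <- if (ns_pairs) {
      cbind(unname(harem_of[st_pairs[, 1L]]), unname(harem_of[st_pairs[, 2L]]))
    } else {
      matrix(character(), 0L, 2L)
    }
    ## same-harem adult-female sibling pairs (maternal half sibs)
    females <- ind$id[ind$role == "female"]
    fem_pairs <- NULL
    for (h in sample(unique(ind$harem))) {
      if (!is.null(fem_pairs) && nrow(fem_pairs) >= sibling_female_pairs) break
      fh <- setdiff(intersect(females, ind$id[ind$harem == h]),
        c(fem_pairs))
      if (length(fh) < 2L) next
      pr <- sample(fh, 2L)
      dam <- new_founder("F")
      mother[match(pr, ind$id)] <- dam
      fem_pairs <- rbind(fem_pairs, pr)
    }
    ped <- Pedigree(rbind(founders, data.frame(
      id = ind$id, sex = sex, birth = birth, death = as.Date(NA),
      mother = mother, father = father, stringsAsFactors = FALSE)))
    ## membership: current harem over [obs - tenure_days, open)
    role_map <- c(stallion = "harem_stallion", female = "adult_female",
      offspring = "subadult")
    cur_start <- obs - tenure_days
    rec <- data.frame(
      id = ind$id, harem = ind$harem,
      start = pmax(cur_start, birth + 1), end = as.Date(NA),
      role = unname(role_map[ind$role]), stringsAsFactors = FALSE
    )
    ## planted familiarity: cross-harem female pairs with a shared past harem
    old_enough <- females[birth[match(females, ind$id)] <
      cur_start - 500]
    fam_pairs <- NULL
    pool <- sample(old_enough)
    while (length(pool) >= 2L &&
      (is.null(fam_pairs) || nrow(fam_pairs) < familiar_pairs)) {
      a <- pool[1L]
      mates <- pool[harem_of[pool] != harem_of[a]]
      if (!length(mates)) break
      b <- mates[1L]
      pool <- setdiff(pool, c(a, b))
      fam_pairs <- rbind(fam_pairs, c(a, b))
    }
    if (!is.null(fam_pairs)) {
      ## the shared spell must fall inside the 2-year window before the
      ## observations: shorten the pair's current tenure and put the shared
      ## 400 days immediately before it
      shared_end <- obs - 300
      for (r in seq_len(nrow(fam_pairs))) {
        ph <- sprintf("OLD%02d", r)
        k <- rec$id %in% fam_pairs[r, ]
        rec$start[k] <- shared_end
        rec <- rbind(rec, data.frame(
          id = fam_pairs[r, ], harem = ph,
          start = shared_end - 400, end = shared_end,
          role = "adult_female", stringsAsFactors = FALSE
        ))
      }
    }
    list(
      pedigree = ped, membership = MembershipHistory(rec),
      observation_date = obs,
      stallion_sibling_harem_pairs = stallion_sibling_harem_pairs,
      planted = list(
        stallion_sibling_pairs = st_pairs,
        female_sibling_pairs = fem_pairs,
        familiar_pairs = fam_pairs,
        familiar_days = 400
      )
    )
  })
}
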