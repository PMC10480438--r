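## Orchestration: trajectories -> dyadic metrics -> structure -> networks ->
## demography joins -> randomisation tests, from one config, with a
## machine-readable results bundle.

#' Pipeline run configuration
#'
#' Inputs are either file paths (trajectory/pedigree/membership CSVs in the
#' package dialects) or in-memory objects (a list of
#' [TrajectorySet-class] sessions, a [Pedigree-class], a
#' [MembershipHistory-class]). Tests are requested by name; each test's
#' required inputs are checked before any computation.
#'
#' @param trajectories path to a trajectory CSV, or list of
#'   [TrajectorySet-class] objects.
#' @param pedigree optional path or [Pedigree-class].
#' @param membership optional path or [MembershipHistory-class].
#' @param observation_date Date of the movement observations (anchors the
#'   2-year familiarity windows); required for demography-linked tests.
#' @param tests character vector of requested test names; see
#'   [runPipeline()].
#' @param sigma,tau_max,min_speed,min_overlap movement-variable parameters.
#' @param cut sub-unit classification cut (m) or `"auto"`.
#' @param d_th harem network threshold (m) or `"auto"` (critical threshold).
#' @param compute_c compute movement similarity (expensive on large herds).
#' @param n_iter,seed randomisation-test parameters.
#' @return configuration list (class `run_config`).
#' @export
runConfig <- function(trajectories, pedigree = NULL, membership = NULL,
                      observation_date = NULL, tests = character(),
                      sigma = 1.2, tau_max = 16, min_speed = 0.05,
                      min_overlap = 25L, cut = "auto", d_th = "auto",
                      compute_c = TRUE, n_iter = 10000L, seed = 20180817L) {
  cfg <- list(
    trajectories = trajectories, pedigree = pedigree,
    membership = membership, observation_date = observation_date,
    tests = tests, sigma = sigma, tau_max = tau_max, min_speed = min_speed,
    min_overlap = as.integer(min_overlap), cut = cut, d_th = d_th,
    compute_c = compute_c, n_iter = as.integer(n_iter),
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

.testRequirements <- list(
  same_harem_distance = "membership",
  same_harem_similarity = c("membership", "similarity"),
  family_vs_harem_distance = c("membership", "pedigree"),
  sibling_stallion_proximity = c("membership", "pedigree"),
  tpast_vs_similarity = c("membership", "similarity", "observation_date"),
  tfuture_vs_similarity = c("membership", "similarity", "observation_date"),
  sibling_cohabitation = c("membership", "pedigree")
)

.haveInput <- function(cfg, what) {
  switch(what,
    membership = !is.null(cfg$membership),
    pedigree = !is.null(cfg$pedigree),
    similarity = isTRUE(cfg$compute_c),
    observation_date = !is.null(cfg$observation_date),
    FALSE
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: session pair metrics,
#' session-averaged metrics, distance distribution and movement-only
#' sub-unit classification, harem gap matrix / critical threshold / harem
#' network / closeness, dyadic demography joins (kinship class, shared days
#' before and after the observations), and the requested randomisation
#' tests. Every stage logs its record count; the bundle is stamped with the
#' seed and a config hash.
#'
#' Available tests: `same_harem_distance` (same-harem dyads are closer;
#' two-sample, less), `same_harem_similarity` (two-sample, greater),
#' `family_vs_harem_distance` (family dyads closer than same-harem
#' non-family; two-sample, less), `sibling_stallion_proximity` (gaps of
#' sibling-stallion harem pairs vs others; two-sample, less),
#' `tpast_vs_similarity` / `tfuture_vs_similarity` (Pearson correlation of
#' shared days with movement similarity among same-harem-level dyads,
#' excluding close kin; correlation, greater), `sibling_cohabitation`
#' (roster reassignment, greater).
#'
#' @param config a [runConfig()].
#' @param out_dir optional directory for the CSV/JSON results bundle.
#' @return list (class `herd_results`): `session_metrics`, `averaged`,
#'   `distribution`, `partition`, `membership_used`, `gaps`, `d_th`,
#'   `network`, `closeness`, `dyads` (join table), `tests`
#'   (results table), `log` (stage record counts), `seed`, `config_hash`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ## fail fast on missing inputs for requested tests
  for (tn in config$tests) {
    req <- .testRequirements[[tn]]
    if (is.null(req)) stop("unknown test: ", tn)
    lack <- req[!vapply(req, function(w) .haveInput(config, w), logical(1L))]
    if (length(lack)) {
      stop("test '", tn, "' needs missing input(s): ",
        paste(lack, collapse = ", "))
    }
  }
  log <- list()
  ## --- inputs
  sessions_ts <- config$trajectories
  if (is.character(sessions_ts)) sessions_ts <- readTrajectories(sessions_ts)
  if (is(sessions_ts, "TrajectorySet")) sessions_ts <- list(sessions_ts)
  ped <- config$pedigree
  if (is.character(ped)) ped <- readPedigree(ped)
  mh <- config$membership
  if (is.character(mh)) mh <- readMembership(mh)
  ## --- movement variables
  sm <- lapply(sessions_ts, function(ts) {
    sessionPairMetrics(ts, sigma = config$sigma, min_speed = config$min_speed,
      tau_max = config$tau_max, min_overlap = config$min_overlap,
      compute_c = config$compute_c)
  })
  log$session_dyads <- vapply(sm, nrow, integer(1L))
  bachelor_ids <- unique(unlist(lapply(sessions_ts, function(ts) {
    st <- trackStatus(ts)
    names(st)[st == "unidentified_bachelor"]
  })))
  avg <- averageSessions(sm, bachelor_ids = bachelor_ids)
  log$averaged_dyads <- nrow(avg)
  ## --- structure
  distribution <- distanceDistribution(avg)
  partition <- classifySubunits(avg, cut = config$cut)
  ## membership for the network layer: observed records if available,
  ## else the movement-only partition
  membership_used <- if (!is.null(mh) && !is.null(config$observation_date)) {
    s <- snapshotAt(mh, config$observation_date)
    setNames(s$harem, s$id)
  } else {
    a <- assignments(partition)
    setNames(paste0("C", a), names(a))
  }
  membership_used <- membership_used[names(membership_used) %in%
    unique(c(avg$id_a, avg$id_b))]
  ## --- networks
  gaps <- haremGapMatrix(avg, membership_used)
  d_th <- if (identical(config$d_th, "auto")) criticalThreshold(gaps) else
    config$d_th
  network <- buildNetwork(gaps, d_th, level = "harem")
  closeness <- closenessCentrality(network)
  ## --- dyadic join table
  dyads <- avg
  dyads$same_harem <- unname(membership_used[dyads$id_a] ==
    membership_used[dyads$id_b])
  if (!is.null(ped)) {
    in_ped <- dyads$id_a %in% pedigreeTable(ped)$id &
      dyads$id_b %in% pedigreeTable(ped)$id
    dyads$kinship <- NA_character_
    dyads$kinship[in_ped] <- kinshipTable(ped, dyads[in_ped, ])
  }
  if (!is.null(mh) && !is.null(config$observation_date)) {
    obs <- as.Date(config$observation_date)
    dyads$t_past <- vapply(seq_len(nrow(dyads)), function(i) {
      sharedDays(mh, dyads$id_a[i], dyads$id_b[i],
        window = c(obs - 730, obs))
    }, numeric(1L))
    dyads$t_future <- vapply(seq_len(nrow(dyads)), function(i) {
      sharedDays(mh, dyads$id_a[i], dyads$id_b[i],
        window = c(obs, obs + 730))
    }, numeric(1L))
  }
  log$join_dyads <- nrow(dyads)
  ## --- randomisation tests
  tests <- list()
  n1 <- list()
  n2 <- list()
  close_kin <- c("parent_offspring", "full_sibling",
    "maternal_half_sibling", "paternal_half_sibling")
  for (tn in config$tests) {
    res <- switch(tn,
      same_harem_distance = {
        x <- dyads$d_bar[dyads$same_harem %in% TRUE]
        y <- dyads$d_bar[dyads$same_harem %in% FALSE]
        n1[[tn]] <- length(x); n2[[tn]] <- length(y)
        permTwoSample(x, y, n_iter = config$n_iter, side = "less",
          seed = config$seed)
      },
      same_harem_similarity = {
        x <- dyads$c_bar[dyads$same_harem %in% TRUE & !is.na(dyads$c_bar)]
        y <- dyads$c_bar[dyads$same_harem %in% FALSE & !is.na(dyads$c_bar)]
        n1[[tn]] <- length(x); n2[[tn]] <- length(y)
        permTwoSample(x, y, n_iter = config$n_iter, side = "greater",
          seed = config$seed)
      },
      family_vs_harem_distance = {
        same <- dyads$same_harem %in% TRUE
        fam <- same & dyads$kinship %in% "parent_offspring"
        n1[[tn]] <- sum(fam); n2[[tn]] <- sum(same & !fam)
        permTwoSample(dyads$d_bar[fam], dyads$d_bar[same & !fam],
          n_iter = config$n_iter, side = "less", seed = config$seed)
      },
      sibling_stallion_proximity = {
        st <- .stallionsOf(mh, config$observation_date, membership_used)
        sib <- .siblingHaremPairs(ped, st)
        gv <- gaps[upper.tri(gaps)]
        key <- outer(rownames(gaps), colnames(gaps), paste)[upper.tri(gaps)]
        is_sib <- key %in% sib
        n1[[tn]] <- sum(is_sib); n2[[tn]] <- sum(!is_sib)
        permTwoSample(gv[is_sib], gv[!is_sib], n_iter = config$n_iter,
          side = "less", seed = config$seed)
      },
      tpast_vs_similarity = {
        ## familiarity effect, close kin excluded
        k <- !is.na(dyads$c_bar) &
          (is.na(dyads$kinship) | !dyads$kinship %in% close_kin)
        n1[[tn]] <- sum(k); n2[[tn]] <- NA
        permCorrelation(dyads$t_past[k], dyads$c_bar[k],
          n_iter = config$n_iter, side = "greater", seed = config$seed)
      },
      tfuture_vs_similarity = {
        k <- !is.na(dyads$c_bar) &
          (is.na(dyads$kinship) | !dyads$kinship %in% close_kin)
        n1[[tn]] <- sum(k); n2[[tn]] <- NA
        permCorrelation(dyads$t_future[k], dyads$c_bar[k],
          n_iter = config$n_iter, side = "greater", seed = config$seed)
      },
      sibling_cohabitation = {
        s <- snapshotAt(mh, config$observation_date)
        rosters <- setNames(s$harem, s$id)[s$role == "adult_female"]
        n1[[tn]] <- length(rosters); n2[[tn]] <- NA
        permSiblingCohabitation(ped, rosters, n_iter = config$n_iter,
          seed = config$seed)
      }
    )
    tests[[tn]] <- res
  }
  test_table <- if (length(tests)) {
    permResultsTable(tests, n1 = n1, n2 = n2)
  } else {
    NULL
  }
  out <- list(
    session_metrics = sm, averaged = avg, distribution = distribution,
    partition = partition, membership_used = membership_used, gaps = gaps,
    d_th = d_th, network = network, closeness = closeness, dyads = dyads,
    tests = test_table, log = log, seed = config$seed,
    config_hash = .configHash(config)
  )
  class(out) <- "herd_results"
  if (!is.null(out_dir)) .writeBundle(out, out_dir)
  out
}

.stallionsOf <- function(mh, date, membership) {
  s <- snapshotAt(mh, date)
  st <- s[s$role == "harem_stallion", ]
  setNames(st$id, st$harem)
}

## unordered harem pairs whose stallions are full or half siblings,
## as "A B" keys with A < B
.siblingHaremPairs <- function(ped, stallions) {
  hs <- names(stallions)
  if (length(hs) < 2L) return(character())
  dy <- t(utils::combn(sort(hs), 2L))
  keep <- stallions[dy[, 1L]] %in% pedigreeTable(ped)$id &
    stallions[dy[, 2L]] %in% pedigreeTable(ped)$id
  dy <- dy[keep, , drop = FALSE]
  if (!nrow(dy)) return(character())
  cls <- kinshipTable(ped, data.frame(id_a = unname(stallions[dy[, 1L]]),
    id_b = unname(stallions[dy[, 2L]])))
  sib <- cls %in% c("full_sibling", "maternal_half_sibling",
    "paternal_half_sibling")
  paste(dy[sib, 1L], dy[sib, 2L])
}

.configHash <- function(config) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  dump <- config
  dump$trajectories <- NULL # objects hash by parameters, not payload
  dump$pedigree <- NULL
  dump$membership <- NULL
  writeLines(paste(names(dump),
    vapply(dump, function(v) paste(format(v), collapse = ","), ""),
    sep = "="), f)
  unname(tools::md5sum(f))
}

.writeBundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writePairMetrics(res$averaged, file.path(out_dir, "averaged_metrics.csv"))
  writePartition(res$partition, file.path(out_dir, "partition.csv"))
  write.csv(res$closeness, file.path(out_dir, "closeness.csv"),
    row.names = FALSE)
  writeNetwork(res$network, file.path(out_dir, "harem_network_edges.csv"))
  write.csv(res$dyads, file.path(out_dir, "dyad_join.csv"), row.names = FALSE)
  if (!is.null(res$tests)) {
    write.csv(res$tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
  }
  summary <- list(
    seed = res$seed, config_hash = res$config_hash, d_th = res$d_th,
    n_subunits = length(unique(assignments(res$partition))),
    log = res$log
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
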