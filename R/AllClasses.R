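## Central S4 containers. Dyadic metric tables (session-level and
## session-averaged pair metrics) are deliberately plain data.frames with a
## documented column contract, in the style of results tables.

setOldClass("igraph")

#' TrajectorySet: one observation session of tracked planar positions
#'
#' Holds time-stamped planar positions (metres) for every tracked individual
#' of a single recording session, together with the frame rate and the
#' identification status of each track. Gaps (missing frames) are allowed;
#' times must be strictly increasing on the common frame grid.
#'
#' @slot session_id single label of the session.
#' @slot frame_rate positions per second (default regime: 12.5).
#' @slot duration session length in seconds.
#' @slot positions data.frame with columns `id`, `frame` (integer, from 0),
#'   `time` (seconds, `frame / frame_rate`), `x`, `y` (metres).
#' @slot status named character vector, one of `"identified"` or
#'   `"unidentified_bachelor"` per track id.
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(
    session_id = "character",
    frame_rate = "numeric",
    duration = "numeric",
    positions = "data.frame",
    status = "character"
  )
)

setValidity("TrajectorySet", function(object) {
  p <- object@positions
  need <- c("id", "frame", "time", "x", "y")
  if (!all(need %in% names(p)))
    return(paste("positions must have columns", paste(need, collapse = ", ")))
  if (length(object@frame_rate) != 1L || object@frame_rate <= 0)
    return("frame_rate must be a single positive number")
  if (nrow(p) == 0L) return("no positions")
  if (any(!is.finite(p$x)) || any(!is.finite(p$y)))
    return("non-finite coordinates")
  ids <- unique(p$id)
  idf <- match(p$id, ids)
  ord <- order(idf, p$frame, method = "radix")
  io <- idf[ord]
  fo <- p$frame[ord]
  same <- io[-1L] == io[-length(io)]
  if (any(same & diff(fo) < 1L))
    return("duplicated or non-increasing (id, frame) rows")
  ## times must sit on the frame grid
  if (max(abs(p$time - p$frame / object@frame_rate)) > 1e-6)
    return("time must equal frame / frame_rate")
  if (any(tabulate(idf) < 2L))
    return("every individual needs at least 2 positions")
  if (!all(ids %in% names(object@status)))
    return("status missing for some track ids")
  if (!all(object@status %in% c("identified", "unidentified_bachelor")))
    return("status values must be 'identified' or 'unidentified_bachelor'")
  TRUE
})

setMethod("show", "TrajectorySet", function(object) {
  ids <- unique(object@positions$id)
  cat("TrajectorySet '", object@session_id, "': ", length(ids),
    " tracks (", sum(object@status[ids] == "unidentified_bachelor"),
    " unidentified bachelors), ", nrow(object@positions), " positions, ",
    object@frame_rate, " fps, ", object@duration, " s\n",
    sep = ""
  )
})

#' HeadingSeries: unit heading vectors and speeds on the frame grid
#'
#' Matrix-backed per-frame unit velocity directions derived from smoothed
#' positions. Entries are `NA` where the heading is invalid (track missing,
#' boundary frame of the central difference, or speed below the minimum).
#'
#' @slot ids track ids (column order of the matrices).
#' @slot frames integer frame indices (row order).
#' @slot time frame times in seconds.
#' @slot hx,hy unit heading components, frames x individuals.
#' @slot speed speeds in m/s, frames x individuals.
#' @slot frame_rate positions per second.
#' @exportClass HeadingSeries
setClass("HeadingSeries",
  representation(
    ids = "character", frames = "integer", time = "numeric",
    hx = "matrix", hy = "matrix", speed = "matrix", frame_rate = "numeric"
  )
)

setValidity("HeadingSeries", function(object) {
  ok <- !is.na(object@hx)
  if (any(is.na(object@hy[ok]))) return("hx/hy validity masks differ")
  nrm <- sqrt(object@hx[ok]^2 + object@hy[ok]^2)
  if (length(nrm) && max(abs(nrm - 1)) > 1e-9)
    return("valid headings must be unit vectors (|h| = 1 within 1e-9)")
  if (ncol(object@hx) != length(object@ids) ||
    nrow(object@hx) != length(object@frames))
    return("matrix dimensions do not match ids/frames")
  TRUE
})

setMethod("show", "HeadingSeries", function(object) {
  cat("HeadingSeries: ", length(object@ids), " tracks x ",
    length(object@frames), " frames; ",
    round(100 * mean(!is.na(object@hx)), 1), "% valid headings\n",
    sep = ""
  )
})

#' DistanceDistribution: kernel density of dyadic distances with peaks
#'
#' @slot sample dyadic distances in metres.
#' @slot grid,density evaluated Gaussian kernel density curve.
#' @slot bandwidth kernel bandwidth used (metres).
#' @slot peaks data.frame `location`, `height` of local maxima above the
#'   height floor, sorted by location.
#' @slot valley location (m) of the density minimum between the two highest
#'   peaks; length 0 when fewer than two peaks exist.
#' @exportClass DistanceDistribution
setClass("DistanceDistribution",
  representation(
    sample = "numeric", grid = "numeric", density = "numeric",
    bandwidth = "numeric", peaks = "data.frame", valley = "numeric"
  )
)

setValidity("DistanceDistribution", function(object) {
  if (any(object@density < 0)) return("density must be non-negative")
  mass <- sum(diff(object@grid) *
    (object@density[-1L] + object@density[-length(object@density)]) / 2)
  if (abs(mass - 1) > 1e-6) return("density must integrate to 1 (+/- 1e-6)")
  if (nrow(object@peaks) > 1L && is.unsorted(object@peaks$location))
    return("peaks must be sorted by location")
  TRUE
})

setMethod("show", "DistanceDistribution", function(object) {
  cat("DistanceDistribution: ", length(object@sample), " dyads, bandwidth ",
    signif(object@bandwidth, 3), " m, ", nrow(object@peaks), " peak(s)",
    if (length(object@valley)) paste0(", valley at ",
      signif(object@valley, 4), " m") else "", "\n",
    sep = ""
  )
})

#' SubunitPartition: movement-only assignment of individuals to sub-units
#'
#' @slot assignment named integer vector, individual id -> cluster label.
#' @slot cut_distance the dendrogram cut distance in metres.
#' @slot singletons ids forming single-member clusters.
#' @exportClass SubunitPartition
setClass("SubunitPartition",
  representation(
    assignment = "integer", cut_distance = "numeric", singletons = "character"
  )
)

setValidity("SubunitPartition", function(object) {
  if (is.null(names(object@assignment))) return("assignment must be named")
  if (anyDuplicated(names(object@assignment)))
    return("every individual labeled exactly once")
  TRUE
})

setMethod("show", "SubunitPartition", function(object) {
  cat("SubunitPartition: ", length(object@assignment), " individuals in ",
    length(unique(object@assignment)), " sub-units (cut ",
    signif(object@cut_distance, 4), " m, ", length(object@singletons),
    " singletons)\n",
    sep = ""
  )
})

#' ProximityNetwork: unweighted graph from thresholded averaged distances
#'
#' Nodes are harems (`level = "harem"`) or individuals within one harem
#' (`level = "within_harem"`); an edge is present exactly when the defining
#' averaged distance is at or below the threshold.
#'
#' @slot graph the underlying igraph object.
#' @slot threshold distance threshold in metres.
#' @slot level `"harem"` or `"within_harem"`.
#' @exportClass ProximityNetwork
setClass("ProximityNetwork",
  representation(graph = "igraph", threshold = "numeric", level = "character")
)

setValidity("ProximityNetwork", function(object) {
  if (!object@level %in% c("harem", "within_harem"))
    return("level must be 'harem' or 'within_harem'")
  if (igraph::any_loop(object@graph)) return("no self-loops allowed")
  TRUE
})

setMethod("show", "ProximityNetwork", function(object) {
  cat("ProximityNetwork (", object@level, "): ",
    igraph::vcount(object@graph), " nodes, ", igraph::ecount(object@graph),
    " edges at threshold ", signif(object@threshold, 4), " m\n",
    sep = ""
  )
})

#' Pedigree: individual life-history records with parent links
#'
#' @slot individuals data.frame with columns `id`, `sex` ("F"/"M"),
#'   `birth` (Date), `death` (Date or NA), `mother`, `father` (ids or NA).
#' @exportClass Pedigree
setClass("Pedigree", representation(individuals = "data.frame"))

setValidity("Pedigree", function(object) {
  d <- object@individuals
  need <- c("id", "sex", "birth", "death", "mother", "father")
  if (!all(need %in% names(d)))
    return(paste("individuals must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(d$id)) return("duplicated individual ids")
  bad <- (!is.na(d$mother) & !d$mother %in% d$id) |
    (!is.na(d$father) & !d$father %in% d$id)
  if (any(bad)) return("parent ids missing from pedigree")
  birth <- setNames(as.numeric(d$birth), d$id)
  for (side in c("mother", "father")) {
    par <- d[[side]]
    k <- !is.na(par)
    if (any(birth[par[k]] >= birth[d$id[k]]))
      return("parents must be born before their offspring")
  }
  ## birth-order constraint above already rules out ancestor cycles
  TRUE
})

setMethod("show", "Pedigree", function(object) {
  d <- object@individuals
  cat("Pedigree: ", nrow(d), " individuals (", sum(d$sex == "F"),
    " F / ", sum(d$sex == "M"), " M), ",
    sum(!is.na(d$mother)), " with known mother\n",
    sep = ""
  )
})

#' MembershipHistory: harem-membership interval records
#'
#' Interval semantics are half-open `[start, end)`; `end = NA` denotes an
#' open (ongoing) interval. Membership is piecewise-constant between records.
#'
#' @slot records data.frame with columns `id`, `harem`, `start` (Date),
#'   `end` (Date or NA), `role` (one of `"subadult"`, `"adult_female"`,
#'   `"harem_stallion"`).
#' @exportClass MembershipHistory
setClass("MembershipHistory", representation(records = "data.frame"))

setValidity("MembershipHistory", function(object) {
  r <- object@records
  need <- c("id", "harem", "start", "end", "role")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  endn <- ifelse(is.na(r$end), Inf, as.numeric(r$end))
  if (any(endn < as.numeric(r$start))) return("end must be >= start")
  o <- order(r$id, r$start)
  rs <- r[o, ]
  same <- rs$id[-1L] == rs$id[-nrow(rs)]
  if (nrow(rs) > 1L) {
    prev_end <- ifelse(is.na(rs$end[-nrow(rs)]), Inf,
      as.numeric(rs$end[-nrow(rs)]))
    if (any(same & as.numeric(rs$start[-1L]) < prev_end))
      return("intervals for one individual must not overlap")
  }
  TRUE
})

setMethod("show", "MembershipHistory", function(object) {
  r <- object@records
  cat("MembershipHistory: ", nrow(r), " interval records, ",
    length(unique(r$id)), " individuals, ", length(unique(r$harem)),
    " harems, ", format(min(r$start)), " .. ",
    if (all(is.na(r$end))) "open" else format(max(r$end, na.rm = TRUE)), "\n",
    sep = ""
  )
})

#' HaremLineage: yearly harem snapshots linked into lineages
#'
#' @slot lineage data.frame, one row per (harem, year): `harem`, `year`,
#'   `ancestor` (harem id in year-1 or NA), `n_common`, `jaccard`,
#'   `start_date` (Date, start of the lineage chain), `new` (logical),
#'   `ended_after` (logical: no descendant in year+1; NA in the final year).
#' @slot members list keyed "year:harem" -> character vector of adult ids.
#' @exportClass HaremLineage
setClass("HaremLineage",
  representation(lineage = "data.frame", members = "list")
)

setValidity("HaremLineage", function(object) {
  l <- object@lineage
  if (anyDuplicated(l[, c("harem", "year")]))
    return("duplicate harem-year rows")
  linked <- !is.na(l$ancestor)
  if (any(l$n_common[linked] < 2))
    return("every ancestor link needs at least two common adults")
  key <- paste(l$ancestor[linked], l$year[linked] - 1L)
  if (anyDuplicated(key)) return("each harem-year has at most one descendant")
  TRUE
})

setMethod("show", "HaremLineage", function(object) {
  l <- object@lineage
  cat("HaremLineage: ", nrow(l), " harem-years over ",
    length(unique(l$year)), " years; ", sum(l$new), " new-harem starts, ",
    sum(!is.na(l$ancestor)), " ancestor links\n",
    sep = ""
  )
})

#' PermutationResult: outcome of a one-sided randomisation test
#'
#' @slot observed observed test statistic.
#' @slot null_sample statistic values under the permutation null.
#' @slot p_value add-one Monte-Carlo p-value, in (0, 1].
#' @slot n_iter number of permutations.
#' @slot scheme `"two_sample"`, `"paired"`, `"correlation"` or
#'   `"roster_reassignment"`.
#' @slot side `"greater"` or `"less"`.
#' @slot seed RNG seed used (NA when inherited from the session RNG).
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    observed = "numeric", null_sample = "numeric", p_value = "numeric",
    n_iter = "integer", scheme = "character", side = "character",
    seed = "numeric"
  )
)

setValidity("PermutationResult", function(object) {
  if (length(object@null_sample) != object@n_iter)
    return("null_sample length must equal n_iter")
  if (object@p_value <= 0 || object@p_value > 1)
    return("p_value must lie in (0, 1]")
  if (!object@side %in% c("greater", "less"))
    return("side must be 'greater' or 'less'")
  TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat("Randomisation test (", object@scheme, ", one-sided ", object@side,
    "): observed = ", signif(object@observed, 5), ", p = ",
    signif(object@p_value, 4), " (n_iter = ", object@n_iter, ")\n",
    sep = ""
  )
})
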