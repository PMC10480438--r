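## Two-layer proximity networks: the harem network and the within-harem
## individual networks, with minimum-spanning-tree critical thresholds,
## hop-count distances and reachable-set closeness centrality.

#' Harem gap matrix
#'
#' Entry (A, B) is the minimum session-averaged distance over all
#' inter-harem member dyads — the spatial gap between two harems. The
#' diagonal is undefined (NA).
#'
#' @param avg averaged pair metrics (`id_a`, `id_b`, `d_bar`).
#' @param membership named vector, individual id -> harem label.
#' @return symmetric numeric matrix of gaps in metres; an error is raised if
#'   any harem pair has no measured dyad.
#' @export
haremGapMatrix <- function(avg, membership) {
  ha <- unname(membership[avg$id_a])
  hb <- unname(membership[avg$id_b])
  keep <- !is.na(ha) & !is.na(hb) & ha != hb
  harems <- sort(unique(unname(membership)))
  if (length(harems) < 2L) stop("need at least 2 harems")
  G <- matrix(NA_real_, length(harems), length(harems),
    dimnames = list(harems, harems))
  if (any(keep)) {
    lo <- pmin(ha[keep], hb[keep])
    hi <- pmax(ha[keep], hb[keep])
    gap <- tapply(avg$d_bar[keep], paste(lo, hi, sep = "\r"), min)
    ks <- strsplit(names(gap), "\r", fixed = TRUE)
    i <- match(vapply(ks, `[`, "", 1L), harems)
    j <- match(vapply(ks, `[`, "", 2L), harems)
    G[cbind(i, j)] <- gap
    G[cbind(j, i)] <- gap
  }
  miss <- which(is.na(G) & row(G) < col(G), arr.ind = TRUE)
  if (nrow(miss)) {
    stop("no measured dyads for harem pair(s): ",
      paste(harems[miss[, 1L]], harems[miss[, 2L]],
        sep = "-", collapse = ", "))
  }
  G
}

## maximum edge weight on a minimum spanning tree of the complete graph on
## the given symmetric distance matrix; 0 for a single node
.mstMaxEdge <- function(M) {
  n <- nrow(M)
  if (n <= 1L) return(0)
  ## +1 shift: zero distances must still be edges in the weighted adjacency
  g <- igraph::graph_from_adjacency_matrix(M + 1, mode = "undirected",
    weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  max(igraph::E(mst)$weight) - 1
}

#' Critical threshold: the smallest distance giving a connected graph
#'
#' Returns the maximum edge weight on a minimum spanning tree of the
#' complete gap graph. The threshold graph (edges where gap <= threshold) is
#' connected at this value and disconnected at any smaller value.
#'
#' @param gaps complete symmetric matrix of harem gaps (m), e.g. from
#'   [haremGapMatrix()].
#' @return threshold in metres (0 for a single node).
#' @export
criticalThreshold <- function(gaps) {
  gaps <- as.matrix(gaps)
  if (nrow(gaps) > 1L && anyNA(gaps[row(gaps) != col(gaps)])) {
    stop("gap matrix must be complete")
  }
  .mstMaxEdge(gaps)
}

#' Build a proximity network from distances and a threshold
#'
#' Edges connect node pairs whose distance is at or below the threshold.
#'
#' @param distances symmetric distance matrix with node names (harem gaps or
#'   individual averaged distances); NA entries never produce an edge.
#' @param threshold distance threshold in metres (> 0).
#' @param level `"harem"` or `"within_harem"`.
#' @return A [ProximityNetwork-class].
#' @export
buildNetwork <- function(distances, threshold,
                         level = c("harem", "within_harem")) {
  level <- match.arg(level)
  stopifnot(threshold > 0)
  M <- as.matrix(distances)
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- as.character(seq_len(nrow(M)))
  }
  A <- !is.na(M) & M <= threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  new("ProximityNetwork", graph = g, threshold = threshold, level = level)
}

#' Per-harem connection thresholds
#'
#' For each harem, the smallest threshold at which all its members are
#' connected (the MST max edge over the members' averaged distances).
#' Individuals that changed harem during the observation period
#' (`switchers`) are excluded from threshold determination; single-member
#' harems get threshold 0.
#'
#' @param avg averaged pair metrics.
#' @param membership named vector id -> harem.
#' @param switchers ids excluded from the threshold computation.
#' @return named numeric vector, harem -> threshold (m).
#' @export
perHaremThresholds <- function(avg, membership, switchers = character()) {
  harems <- sort(unique(unname(membership)))
  out <- setNames(numeric(length(harems)), harems)
  for (h in harems) {
    ids <- setdiff(names(membership)[membership == h], switchers)
    if (length(ids) == 0L) {
      stop("harem ", h, " has no non-switcher members")
    }
    if (length(ids) == 1L) {
      out[h] <- 0
      next
    }
    M <- .distMatrix(avg, ids)
    if (anyNA(M)) stop("missing averaged distances within harem ", h)
    out[h] <- .mstMaxEdge(M)
  }
  out
}

#' Within-harem individual networks
#'
#' Builds one individual-level proximity network per harem at that harem's
#' own connection threshold (see [perHaremThresholds()]); switchers are
#' excluded from threshold determination but retained as nodes.
#'
#' @inheritParams perHaremThresholds
#' @return named list of [ProximityNetwork-class] objects.
#' @export
withinHaremNetworks <- function(avg, membership, switchers = character()) {
  th <- perHaremThresholds(avg, membership, switchers)
  out <- lapply(names(th), function(h) {
    ids <- names(membership)[membership == h]
    M <- .distMatrix(avg, ids)
    buildNetwork(M, threshold = max(th[h], .Machine$double.eps),
      level = "within_harem")
  })
  setNames(out, names(th))
}

#' Hop-count network distance
#'
#' @param net a [ProximityNetwork-class].
#' @param a,b node names.
#' @return unweighted shortest-path length (Inf when disconnected).
#' @export
networkDistance <- function(net, a, b) {
  g <- networkGraph(net)
  nodes <- igraph::V(g)$name
  if (!a %in% nodes || !b %in% nodes) {
    stop("unknown node(s): ", paste(setdiff(c(a, b), nodes), collapse = ", "))
  }
  as.numeric(igraph::distances(g, v = a, to = b))
}

#' Closeness centrality on the reachable set
#'
#' For each node, the number of other reachable nodes divided by the sum of
#' hop distances to them (the reciprocal of the mean shortest-path distance
#' from all other reachable nodes). Isolated nodes get 0. On a connected
#' graph this lies in (0, 1].
#'
#' @param net a [ProximityNetwork-class].
#' @return data.frame `node`, `closeness`, `degree`.
#' @export
closenessCentrality <- function(net) {
  g <- networkGraph(net)
  D <- igraph::distances(g)
  cl <- apply(D, 1L, function(row) {
    reach <- is.finite(row) & row > 0
    if (!any(reach)) return(0)
    sum(reach) / sum(row[reach])
  })
  data.frame(
    node = igraph::V(g)$name, closeness = as.numeric(cl),
    degree = as.integer(igraph::degree(g)), stringsAsFactors = FALSE
  )
}

#' Mean closest-bachelor distance per harem
#'
#' Per session, the minimum 5-min distance between any bachelor track and
#' any member of the harem; averaged over the sessions where bachelors were
#' tracked. Sessions without a bachelor dyad are skipped with a warning.
#'
#' @param sessions list of session pair-metric data.frames (including
#'   bachelor dyads).
#' @param membership named vector id -> harem (harem-living individuals).
#' @param bachelor_ids bachelor track ids.
#' @return named numeric vector, harem -> metres.
#' @export
bachelorProximity <- function(sessions, membership, bachelor_ids) {
  harems <- sort(unique(unname(membership)))
  acc <- matrix(NA_real_, length(sessions), length(harems),
    dimnames = list(NULL, harems))
  for (s in seq_along(sessions)) {
    m <- sessions[[s]]
    ba <- m$id_a %in% bachelor_ids
    bb <- m$id_b %in% bachelor_ids
    one <- xor(ba, bb)
    if (!any(one)) {
      warning("session ", s, " has no bachelor dyads; skipped")
      next
    }
    member <- ifelse(ba[one], m$id_b[one], m$id_a[one])
    h <- unname(membership[member])
    d <- m$d_5min[one]
    ok <- !is.na(h)
    mins <- tapply(d[ok], h[ok], min)
    acc[s, names(mins)] <- mins
  }
  colMeans(acc, na.rm = TRUE)
}

#' Threshold robustness report
#'
#' Rebuilds the harem network at `base_threshold * (1 - factor)` and
#' `* (1 + factor)`, reports closeness tables, connectivity of each variant,
#' and the Spearman rank correlation of closeness against the base network.
#'
#' @param gaps symmetric gap matrix.
#' @param base_threshold base threshold in metres.
#' @param factor relative perturbation (default 0.10).
#' @return list with elements `thresholds`, `closeness` (list of three
#'   tables: lower/base/upper), `connected` (logical vector), and
#'   `rank_correlation` (lower-vs-base, upper-vs-base).
#' @export
thresholdRobustness <- function(gaps, base_threshold, factor = 0.10) {
  th <- c(
    lower = base_threshold * (1 - factor),
    base = base_threshold,
    upper = base_threshold * (1 + factor)
  )
  nets <- lapply(th, function(t) buildNetwork(gaps, t, level = "harem"))
  cls <- lapply(nets, closenessCentrality)
  connected <- vapply(nets, function(n) {
    igraph::is_connected(networkGraph(n))
  }, logical(1L))
  ## rank correlation is undefined when one side has tied-everywhere
  ## closeness (e.g. a complete graph); identical tables report 1
  rank_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      return(if (isTRUE(all.equal(a, b))) 1 else NA_real_)
    }
    cor(a, b, method = "spearman")
  }
  rc <- c(
    lower = rank_cor(cls$lower$closeness, cls$base$closeness),
    upper = rank_cor(cls$upper$closeness, cls$base$closeness)
  )
  list(thresholds = th, closeness = cls, connected = connected,
    rank_correlation = rc)
}

#' Export a ProximityNetwork
#'
#' Writes the edge list as CSV (`node_a,node_b`) and, when `graphml` is
#' given, a GraphML file with optional node attributes.
#'
#' @param net a [ProximityNetwork-class].
#' @param path edge-list CSV path.
#' @param graphml optional GraphML output path.
#' @param node_attrs optional data.frame with a `node` column plus attribute
#'   columns (e.g. harem size, closeness, stallion experience).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, graphml = NULL, node_attrs = NULL) {
  write.csv(networkEdges(net), path, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- networkGraph(net)
    if (!is.null(node_attrs)) {
      idx <- match(igraph::V(g)$name, node_attrs$node)
      for (col in setdiff(names(node_attrs), "node")) {
        g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
      }
    }
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
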