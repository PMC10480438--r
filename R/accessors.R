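## Accessors for the S4 containers (use these, not direct slot access).

#' Accessors for herdstruct objects
#'
#' Small family of extractor generics for the package's S4 containers.
#'
#' @param x the object.
#' @return The corresponding slot content; see the class documentation.
#' @name accessors
#' @aliases sessionId frameRate trackIds trackPositions trackStatus
#'   densityCurve densityPeaks densityValley assignments cutDistance
#'   networkGraph networkThreshold networkNodes networkEdges pedigreeTable
#'   membershipRecords lineageTable pvalue nullSample observedStat
NULL

#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))
#' @rdname accessors
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))
#' @rdname accessors
#' @export
setGeneric("trackStatus", function(x) standardGeneric("trackStatus"))

setMethod("sessionId", "TrajectorySet", function(x) x@session_id)
setMethod("frameRate", "TrajectorySet", function(x) x@frame_rate)
setMethod("trackIds", "TrajectorySet", function(x) unique(x@positions$id))
setMethod("trackPositions", "TrajectorySet", function(x) x@positions)
setMethod("trackStatus", "TrajectorySet", function(x) x@status)

setMethod("frameRate", "HeadingSeries", function(x) x@frame_rate)
setMethod("trackIds", "HeadingSeries", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("densityCurve", function(x) standardGeneric("densityCurve"))
#' @rdname accessors
#' @export
setGeneric("densityPeaks", function(x) standardGeneric("densityPeaks"))
#' @rdname accessors
#' @export
setGeneric("densityValley", function(x) standardGeneric("densityValley"))

setMethod("densityCurve", "DistanceDistribution", function(x) {
  data.frame(distance = x@grid, density = x@density)
})
setMethod("densityPeaks", "DistanceDistribution", function(x) x@peaks)
setMethod("densityValley", "DistanceDistribution", function(x) x@valley)

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("cutDistance", function(x) standardGeneric("cutDistance"))

setMethod("assignments", "SubunitPartition", function(x) x@assignment)
setMethod("cutDistance", "SubunitPartition", function(x) x@cut_distance)

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @rdname accessors
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

setMethod("networkGraph", "ProximityNetwork", function(x) x@graph)
setMethod("networkThreshold", "ProximityNetwork", function(x) x@threshold)
setMethod("networkNodes", "ProximityNetwork", function(x) {
  igraph::V(x@graph)$name
})
setMethod("networkEdges", "ProximityNetwork", function(x) {
  e <- igraph::as_edgelist(x@graph)
  data.frame(node_a = e[, 1], node_b = e[, 2])
})

#' @rdname accessors
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))
#' @rdname accessors
#' @export
setGeneric("membershipRecords", function(x) standardGeneric("membershipRecords"))
#' @rdname accessors
#' @export
setGeneric("lineageTable", function(x) standardGeneric("lineageTable"))

setMethod("pedigreeTable", "Pedigree", function(x) x@individuals)
setMethod("membershipRecords", "MembershipHistory", function(x) x@records)
setMethod("lineageTable", "HaremLineage", function(x) x@lineage)

#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))
#' @rdname accessors
#' @export
setGeneric("nullSample", function(x) standardGeneric("nullSample"))
#' @rdname accessors
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

setMethod("pvalue", "PermutationResult", function(x) x@p_value)
setMethod("nullSample", "PermutationResult", function(x) x@null_sample)
setMethod("observedStat", "PermutationResult", function(x) x@observed)
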