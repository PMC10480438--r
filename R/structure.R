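## Detection of the social levels from the dyadic distance distribution and
## movement-only classification of individuals into sub-units (harems).

#' Kernel density of dyadic distances, with peaks and valley
#'
#' Gaussian kernel density of the dyadic distance sample. In a multilevel
#' herd the density is bimodal: a low-distance peak from within-harem dyads
#' and a high-distance peak from the herd level; the valley between the two
#' highest peaks is the natural movement-only cut between the levels.
#'
#' @param d numeric vector of dyadic distances (m), or a pair-metrics
#'   data.frame with a `d_bar` or `d_5min` column.
#' @param bandwidth kernel bandwidth in metres; default is the
#'   Sheather-Jones plug-in (`stats::bw.SJ`), which adapts to the narrow
#'   sub-unit mode that a global rule-of-thumb bandwidth over-smooths.
#' @param peak_floor minimum peak height as a fraction of the density
#'   maximum (default 0.05), suppressing noise peaks.
#' @param prominence two local maxima count as separate peaks only if the
#'   density between them dips below `prominence` times the lower of the two
#'   heights (default 0.15); ripples on a broad mode are thereby merged into
#'   one peak, and only modes separated by a deep valley — the regime where
#'   a distance cut between social levels is meaningful — are reported.
#' @return A [DistanceDistribution-class].
#' @export
distanceDistribution <- function(d, bandwidth = NULL, peak_floor = 0.05,
                                 prominence = 0.15) {
  if (is.data.frame(d)) {
    col <- intersect(c("d_bar", "d_5min"), names(d))[1L]
    if (is.na(col)) stop("no distance column (d_bar or d_5min) found")
    d <- d[[col]]
  }
  d <- d[is.finite(d)]
  if (length(d) < 10L) stop("need at least 10 dyadic distances")
  den <- if (is.null(bandwidth)) {
    density(d, bw = "SJ", n = 4096L, cut = 8)
  } else {
    density(d, bw = bandwidth, n = 4096L, cut = 8)
  }
  y <- den$y
  ## renormalise the binned curve to unit mass on its own grid
  y <- y / sum(diff(den$x) * (y[-1L] + y[-length(y)]) / 2)
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] &
    y[2:(n - 1L)] >= y[3:n], FALSE)
  is_peak <- is_peak & y >= peak_floor * max(y)
  cand <- data.frame(idx = which(is_peak), location = den$x[is_peak],
    height = y[is_peak])
  ## prominence merging: keep a candidate only if it is separated from every
  ## kept peak by a sufficiently deep dip
  cand <- cand[order(cand$height, decreasing = TRUE), , drop = FALSE]
  kept <- integer()
  for (r in seq_len(nrow(cand))) {
    ok <- TRUE
    for (q in kept) {
      rng <- sort(c(cand$idx[r], cand$idx[q]))
      dip <- min(y[rng[1L]:rng[2L]])
      if (dip > prominence * min(cand$height[r], cand$height[q])) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, r)
  }
  peaks <- cand[kept, c("location", "height")]
  peaks <- peaks[order(peaks$location), , drop = FALSE]
  rownames(peaks) <- NULL
  ## valley: density minimum between the two main peaks. The low-distance
  ## (sub-unit) peak is the first peak; the herd-level mode is the highest
  ## peak beyond it — on multi-scale data the broad herd mode can carry
  ## minor bumps, so "first vs highest-beyond" is used rather than the two
  ## highest peaks overall.
  valley <- numeric()
  if (nrow(peaks) >= 2L) {
    lo <- peaks$location[1L]
    rest <- peaks[-1L, , drop = FALSE]
    hi <- rest$location[which.max(rest$height)]
    between <- which(den$x > lo & den$x < hi)
    valley <- den$x[between[which.min(y[between])]]
  }
  new("DistanceDistribution",
    sample = as.numeric(d), grid = den$x, density = y,
    bandwidth = den$bw, peaks = peaks, valley = valley
  )
}

## symmetric distance matrix from an averaged pair-metrics table; dyads
## without a measured distance are filled with `fill`
.distMatrix <- function(avg, ids = NULL, fill = NA_real_) {
  if (is.null(ids)) ids <- sort(unique(c(avg$id_a, avg$id_b)))
  M <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  keep <- avg$id_a %in% ids & avg$id_b %in% ids
  a <- match(avg$id_a[keep], ids)
  b <- match(avg$id_b[keep], ids)
  col <- intersect(c("d_bar", "d_5min"), names(avg))[1L]
  M[cbind(a, b)] <- avg[[col]][keep]
  M[cbind(b, a)] <- avg[[col]][keep]
  diag(M) <- 0
  M
}

#' Movement-only classification of individuals into sub-units
#'
#' Single-linkage agglomerative clustering on the session-averaged pairwise
#' distances, with the dendrogram cut at `cut` metres. Single linkage is
#' used because cutting it at c is exactly the connected components of the
#' graph that joins dyads closer than c — the same construction as the
#' proximity networks. With `cut = "auto"` the cut is placed at the valley
#' of the distance density.
#'
#' @param avg averaged pair metrics (data.frame with `id_a`, `id_b`,
#'   `d_bar`), identified individuals only.
#' @param cut cut distance in metres, or `"auto"`.
#' @param bandwidth passed to [distanceDistribution()] when `cut = "auto"`.
#' @return A [SubunitPartition-class].
#' @export
classifySubunits <- function(avg, cut = "auto", bandwidth = NULL) {
  ids <- sort(unique(c(avg$id_a, avg$id_b)))
  if (identical(cut, "auto")) {
    dd <- distanceDistribution(avg, bandwidth = bandwidth)
    if (!length(dd@valley)) {
      stop("distance density has no valley (fewer than two peaks); ",
        "supply a manual cut distance")
    }
    cut <- dd@valley
  }
  stopifnot(is.numeric(cut), length(cut) == 1L, cut > 0)
  M <- .distMatrix(avg, ids)
  if (anyNA(M)) {
    ## unmeasured dyads cannot join clusters directly: park them far beyond
    ## any cut of interest
    M[is.na(M)] <- 10 * max(M, na.rm = TRUE) + cut
  }
  hc <- hclust(as.dist(M), method = "single")
  lab <- cutree(hc, h = cut)
  sizes <- table(lab)
  new("SubunitPartition",
    assignment = setNames(as.integer(lab), ids),
    cut_distance = cut,
    singletons = ids[lab %in% as.integer(names(sizes)[sizes == 1L])]
  )
}

#' Annotate dyads with their social category
#'
#' Categories follow the nested levels of the society: `same_family` (an
#' adult female and her 1-5 year old pre-dispersal offspring, or two such
#' offspring of the same female; current-year foals are not family members),
#' `same_harem` (same harem, different family), `diff_harem` (two
#' harem-living individuals of different harems), `bachelor_harem` (a
#' bachelor and a harem-living individual).
#'
#' @param metrics pair-metrics data.frame (`id_a`, `id_b`).
#' @param harem named vector id -> harem label (harem-living individuals).
#' @param mother named vector id -> mother id for pre-dispersal offspring
#'   counted in families (exclude current-year foals upstream).
#' @param bachelor_ids bachelor track ids.
#' @return factor of categories aligned with `metrics` rows; NA where a
#'   dyad cannot be annotated (e.g. bachelor-bachelor).
#' @export
annotateDyads <- function(metrics, harem, mother = character(),
                          bachelor_ids = character()) {
  a <- metrics$id_a
  b <- metrics$id_b
  ba <- a %in% bachelor_ids
  bb <- b %in% bachelor_ids
  ha <- unname(harem[a])
  hb <- unname(harem[b])
  fam_of <- function(id) ifelse(id %in% names(mother),
    unname(mother[id]), id)
  same_fam <- fam_of(a) == fam_of(b)
  out <- rep(NA_character_, nrow(metrics))
  out[ba & bb] <- NA # bachelor pairs cannot be classified
  one_bach <- xor(ba, bb)
  out[one_bach & (!is.na(ha) | !is.na(hb))] <- "bachelor_harem"
  both <- !ba & !bb & !is.na(ha) & !is.na(hb)
  out[both & ha != hb] <- "diff_harem"
  out[both & ha == hb] <- "same_harem"
  out[both & ha == hb & same_fam] <- "same_family"
  factor(out, levels = c("same_family", "same_harem", "diff_harem",
    "bachelor_harem"))
}

#' Per-category summaries of distance and movement similarity
#'
#' Medians, quartiles and sample sizes of the dyadic distance and (when
#' present) similarity per social category — the table behind the
#' family-to-herd contrast of the two movement variables.
#'
#' @param metrics pair-metrics data.frame with a distance column (`d_bar` or
#'   `d_5min`) and optionally `c_bar` / `c_5min`.
#' @param labels factor/character of social categories per row (see
#'   [annotateDyads()]); NA rows are excluded with a message.
#' @return data.frame, one row per category: `category`, `n`, `d_median`,
#'   `d_q25`, `d_q75`, `n_c`, `c_median`, `c_q25`, `c_q75`.
#' @export
levelContrast <- function(metrics, labels) {
  known <- c("same_family", "same_harem", "diff_harem", "bachelor_harem")
  labels <- as.character(labels)
  bad <- !is.na(labels) & !labels %in% known
  if (any(bad)) {
    stop("unknown annotation(s): ", paste(unique(labels[bad]), collapse = ", "))
  }
  drop <- is.na(labels)
  if (any(drop)) {
    message("excluding ", sum(drop), " dyad(s) without annotation")
  }
  metrics <- metrics[!drop, , drop = FALSE]
  labels <- labels[!drop]
  dcol <- intersect(c("d_bar", "d_5min"), names(metrics))[1L]
  ccol <- intersect(c("c_bar", "c_5min"), names(metrics))[1L]
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(c(n = 0, med = NA_real_, q25 = NA_real_, q75 = NA_real_))
    }
    c(n = length(v), med = median(v), q25 = unname(quantile(v, 0.25)),
      q75 = unname(quantile(v, 0.75)))
  }
  rows <- lapply(known, function(cat) {
    sub <- metrics[labels == cat, , drop = FALSE]
    dq <- qs(sub[[dcol]])
    cq <- if (!is.na(ccol)) qs(sub[[ccol]]) else
      c(n = 0, med = NA_real_, q25 = NA_real_, q75 = NA_real_)
    data.frame(category = cat, n = dq["n"], d_median = dq["med"],
      d_q25 = dq["q25"], d_q75 = dq["q75"], n_c = cq["n"],
      c_median = cq["med"], c_q25 = cq["q25"], c_q75 = cq["q75"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a SubunitPartition to CSV
#'
#' @param partition a [SubunitPartition-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(partition, path) {
  a <- assignments(partition)
  write.csv(data.frame(individual_id = names(a), cluster = unname(a)),
    path, row.names = FALSE)
  invisible(path)
}
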