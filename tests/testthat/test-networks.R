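avgFromDistMatrix <- function(M) {
  ids <- rownames(M)
  dy <- t(utils::combn(ids, 2L))
  data.frame(id_a = dy[, 1L], id_b = dy[, 2L], d_bar = M[dy],
    stringsAsFactors = FALSE)
}

test_that("harem gap matrix is the minimum cross-member distance", {
  avg <- data.frame(
    id_a = c("a1", "a1", "a2", "a2", "a1", "b1"),
    id_b = c("b1", "b2", "b1", "b2", "a2", "b2"),
    d_bar = c(40, 60, 70, 90, 5, 8)
  )
  memb <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  G <- haremGapMatrix(avg, memb)
  expect_equal(G["A", "B"], 40)
  expect_equal(G["B", "A"], 40)
  expect_true(is.na(G["A", "A"]))

  ## 3 harems against exhaustive enumeration of member dyads
  set.seed(5)
  ids <- sprintf("i%02d", 1:9)
  memb3 <- setNames(rep(c("A", "B", "C"), each = 3L), ids)
  dy <- t(utils::combn(ids, 2L))
  avg3 <- data.frame(id_a = dy[, 1L], id_b = dy[, 2L],
    d_bar = runif(nrow(dy), 10, 200))
  G3 <- haremGapMatrix(avg3, memb3)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    manual <- Inf
    for (r in seq_len(nrow(avg3))) {
      ha <- memb3[[avg3$id_a[r]]]
      hb <- memb3[[avg3$id_b[r]]]
      if (setequal(c(ha, hb), pair)) manual <- min(manual, avg3$d_bar[r])
    }
    expect_equal(G3[pair[1L], pair[2L]], manual)
  }

  ## unmeasured harem pair is an error
  avg_miss <- avg[avg$id_b != "b1" | avg$id_a != "a1", ]
  avg_miss <- avg_miss[!(avg_miss$id_a %in% c("a1", "a2") &
    avg_miss$id_b %in% c("b1", "b2")), ]
  expect_error(haremGapMatrix(avg_miss, memb), "no measured dyads")
})

test_that("critical threshold is the MST max edge and the oracle scan value", {
  G <- matrix(c(0, 10, 50, 10, 0, 20, 50, 20, 0), 3, 3,
    dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_equal(criticalThreshold(G), 20)

  ## chain of 10 harems with gaps 5, 10, ..., 45 plus larger cross gaps
  n <- 10L
  M <- matrix(500, n, n) + matrix(runif(n * n, 0, 50), n, n)
  M <- (M + t(M)) / 2
  for (i in 1:(n - 1L)) M[i, i + 1L] <- M[i + 1L, i] <- 5 * i
  diag(M) <- 0
  dimnames(M) <- list(paste0("H", 1:n), paste0("H", 1:n))
  expect_equal(criticalThreshold(M), 45)
  expect_equal(oracle_critical_threshold(M), 45)

  two <- matrix(c(0, 33.5, 33.5, 0), 2, 2,
    dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(criticalThreshold(two), 33.5)
  expect_equal(criticalThreshold(matrix(0, 1, 1, dimnames = list("A", "A"))), 0)

  for (case in 1:10) {
    M <- randDistMatrix(sample(4:12, 1L), seed = 400 + case)
    expect_equal(criticalThreshold(M), oracle_critical_threshold(M),
      tolerance = 1e-12)
  }
})

test_that("threshold graph edges match the predicate; connectivity at d_th", {
  M <- randDistMatrix(6, seed = 17)
  th <- median(M[upper.tri(M)])
  net <- buildNetwork(M, th)
  ed <- networkEdges(net)
  got <- sort(paste(pmin(ed$node_a, ed$node_b), pmax(ed$node_a, ed$node_b)))
  dy <- t(utils::combn(rownames(M), 2L))
  want <- sort(paste(dy[, 1L], dy[, 2L])[M[dy] <= th])
  expect_equal(got, want)

  expect_equal(nrow(networkEdges(buildNetwork(M, min(M[upper.tri(M)]) / 2))),
    0L)
  crit <- criticalThreshold(M)
  expect_true(igraph::is_connected(networkGraph(buildNetwork(M, crit))))
  expect_false(igraph::is_connected(networkGraph(
    buildNetwork(M, crit * 0.999))))
})

test_that("per-harem thresholds connect exactly the non-switcher members", {
  M <- matrix(c(0, 12, 40, 12, 0, 18, 40, 18, 0), 3, 3,
    dimnames = list(c("m1", "m2", "m3"), c("m1", "m2", "m3")))
  avg <- avgFromDistMatrix(M)
  memb <- c(m1 = "H", m2 = "H", m3 = "H")
  expect_equal(perHaremThresholds(avg, memb)[["H"]], 18)

  ## switcher excluded from determination
  memb2 <- c(m1 = "H", m2 = "H", m3 = "H")
  expect_equal(perHaremThresholds(avg, memb2, switchers = "m3")[["H"]], 12)

  ## single-member harem
  expect_equal(perHaremThresholds(avg[0, ], c(z = "Z"))[["Z"]], 0)

  ## 5-member random harem vs exhaustive threshold scan
  for (case in 1:6) {
    M5 <- randDistMatrix(5, seed = 500 + case)
    ids <- rownames(M5)
    th <- perHaremThresholds(avgFromDistMatrix(M5),
      setNames(rep("H", 5), ids))[["H"]]
    expect_equal(th, oracle_critical_threshold(M5), tolerance = 1e-12)
  }

  ## within-harem networks keep switchers as nodes
  nets <- withinHaremNetworks(avg, memb2, switchers = "m3")
  expect_setequal(networkNodes(nets$H), c("m1", "m2", "m3"))
})

test_that("network hop distances match breadth-first search", {
  M <- matrix(100, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  M[1, 2] <- M[2, 1] <- 1
  M[2, 3] <- M[3, 2] <- 1
  diag(M) <- 0
  net <- buildNetwork(M, 1)
  expect_equal(networkDistance(net, "A", "B"), 1)
  expect_equal(networkDistance(net, "A", "C"), 2)
  expect_error(networkDistance(net, "A", "Q"), "unknown node")

  for (case in 1:6) {
    M8 <- randDistMatrix(8, seed = 600 + case)
    th <- quantile(M8[upper.tri(M8)], 0.35)
    net8 <- buildNetwork(M8, th)
    adj <- M8 <= th
    diag(adj) <- FALSE
    for (a in 1:8) {
      d_oracle <- oracle_bfs(adj, a)
      for (b in seq(1, 8, by = 2)) {
        if (a == b) next
        expect_equal(networkDistance(net8, rownames(M8)[a], rownames(M8)[b]),
          d_oracle[b])
      }
    }
  }
})

test_that("closeness uses the reachable-set formula", {
  ## star with 4 leaves: center 1.0, each leaf 4/7
  M <- matrix(100, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  M[1, 2:5] <- M[2:5, 1] <- 1
  diag(M) <- 0
  cl <- closenessCentrality(buildNetwork(M, 1))
  expect_equal(cl$closeness[cl$node == "v1"], 1)
  expect_equal(cl$closeness[cl$node != "v1"], rep(4 / 7, 4))

  ## complete graph: everyone 1.0
  K <- matrix(1, 4, 4, dimnames = list(paste0("k", 1:4), paste0("k", 1:4)))
  diag(K) <- 0
  expect_equal(closenessCentrality(buildNetwork(K, 2))$closeness, rep(1, 4))

  ## random connected graphs vs the BFS oracle; isolated node -> 0
  for (case in 1:6) {
    M10 <- randDistMatrix(10, seed = 700 + case)
    th <- quantile(M10[upper.tri(M10)], 0.3)
    cl10 <- closenessCentrality(buildNetwork(M10, th))
    adj <- M10 <= th
    diag(adj) <- FALSE
    expect_equal(cl10$closeness, oracle_closeness(adj), tolerance = 1e-12)
  }
})

test_that("bachelor proximity averages session minima per harem", {
  mk <- function(d_ab, d_bb) {
    data.frame(session = "S",
      id_a = c("m1", "m2", "m1"), id_b = c("bach1", "bach1", "m2"),
      d_5min = c(d_ab, d_bb, 7), n_overlap = 10L)
  }
  memb <- c(m1 = "A", m2 = "A")
  out <- bachelorProximity(list(mk(30, 45)), memb, "bach1")
  expect_equal(out[["A"]], 30)
  out2 <- bachelorProximity(list(mk(10, 50), mk(20, 60)), memb, "bach1")
  expect_equal(out2[["A"]], 15)
  nob <- data.frame(session = "S", id_a = "m1", id_b = "m2", d_5min = 5,
    n_overlap = 10L)
  expect_warning(bachelorProximity(list(nob, mk(30, 45)), memb, "bach1"),
    "no bachelor dyads")
})

test_that("threshold robustness reports variants and rank correlations", {
  ## complete graph far below threshold: identical edge sets at all variants
  K <- matrix(runif(25, 1, 2), 5, 5)
  K <- (K + t(K)) / 2
  diag(K) <- 0
  dimnames(K) <- list(paste0("n", 1:5), paste0("n", 1:5))
  rob <- thresholdRobustness(K, 100)
  expect_true(all(rob$connected))
  expect_equal(networkEdges(buildNetwork(K, 90)),
    networkEdges(buildNetwork(K, 110)))

  ## chain at criticality: lower variant disconnects, reported not an error
  n <- 6L
  M <- matrix(500, n, n)
  for (i in 1:(n - 1L)) M[i, i + 1L] <- M[i + 1L, i] <- 10 * i
  diag(M) <- 0
  dimnames(M) <- list(paste0("c", 1:n), paste0("c", 1:n))
  rob2 <- thresholdRobustness(M, criticalThreshold(M))
  expect_false(rob2$connected[["lower"]])
  expect_true(rob2$connected[["base"]])

  ## rank correlation equals a direct recomputation
  M2 <- randDistMatrix(9, seed = 123)
  base <- criticalThreshold(M2) * 1.1
  rob3 <- thresholdRobustness(M2, base)
  direct <- cor(
    closenessCentrality(buildNetwork(M2, base * 0.9))$closeness,
    closenessCentrality(buildNetwork(M2, base))$closeness,
    method = "spearman"
  )
  expect_equal(rob3$rank_correlation[["lower"]], direct)
})

test_that("edge sets grow with threshold and hop metric is a metric", {
  M <- randDistMatrix(10, seed = 999)
  th <- sort(sample(M[upper.tri(M)], 4L))
  prev <- NULL
  for (t in th) {
    e <- networkEdges(buildNetwork(M, t))
    key <- paste(e$node_a, e$node_b)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
  net <- buildNetwork(M, criticalThreshold(M))
  D <- igraph::distances(networkGraph(net))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(D[i, j], D[i, k] + D[k, j])
  }
})

test_that("network export writes edge list and GraphML", {
  M <- randDistMatrix(5, seed = 31)
  net <- buildNetwork(M, criticalThreshold(M))
  f <- withr::local_tempfile(fileext = ".csv")
  g <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, f, graphml = g,
    node_attrs = data.frame(node = networkNodes(net),
      closeness = closenessCentrality(net)$closeness))
  expect_equal(nrow(read.csv(f)), nrow(networkEdges(net)))
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gg), 5)
  expect_true("closeness" %in% igraph::vertex_attr_names(gg))
})
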