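toy <- toy_fixture()
g <- toy$graph

test_that("edge weighting restricts similarity support to the adjacency", {
  w <- build_weighted_graph(g, "cns1")
  key <- paste(w$nodes[w$edges[, 1]], w$nodes[w$edges[, 2]])
  wts <- stats::setNames(w$weights, key)
  expect_equal(round(unname(wts["George Ying"]), 2), 0.41)
  # non-edges carry no weight: only the 8 edges exist
  expect_equal(length(w$weights), 8L)
  expect_false("George Pitt" %in% key || "Pitt George" %in% key)
  # adjacency similarity yields the unweighted graph
  wa <- build_weighted_graph(g, "adjacency")
  expect_equal(wa$weights, rep(1, 8))
  # high-attribute-similarity non-adjacent pair stays at zero weight
  S <- similarity_matrix(g, "cns1", full = TRUE)
  expect_gt(S["George", "Pitt"], 0)
})

test_that("SLPA recovers bridged cliques and handles degenerate graphs", {
  w <- bridged_cliques()
  hits <- sum(vapply(1:100, function(s) {
    fit <- slpa(w, iterations = 20, seed = s)
    nmi(clique_truth(), fit$partition) == 1
  }, logical(1)))
  expect_gte(hits, 95)

  single <- weighted_graph("a", matrix(integer(0), ncol = 2), numeric(0))
  fit1 <- slpa(single, iterations = 5, seed = 1)
  expect_equal(nrow(fit1$partition), 1L)
  expect_equal(length(unique(fit1$partition$community)), 1L)

  w0 <- weighted_graph(paste0("v", 1:4), rbind(c(1, 2), c(3, 4)), c(0, 0))
  fit0 <- slpa(w0, iterations = 10, seed = 3)  # must terminate
  expect_equal(nrow(fit0$partition), 4L)
  expect_error(slpa(w, iterations = 0), ">= 1")
})

test_that("weighted modularity matches closed-form cases and igraph", {
  tri2 <- weighted_graph(paste0("n", 1:6),
                         rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)),
                         rep(2, 6))
  comp <- tibble::tibble(node = paste0("n", 1:6),
                         community = rep(c("a", "b"), each = 3))
  expect_equal(weighted_modularity(tri2, comp), 0.5)
  allone <- tibble::tibble(node = paste0("n", 1:6), community = "x")
  expect_equal(weighted_modularity(tri2, allone), 0)

  edge1 <- weighted_graph(c("a", "b"), rbind(c(1, 2)), 1)
  singletons <- tibble::tibble(node = c("a", "b"), community = c("p", "q"))
  expect_equal(weighted_modularity(edge1, singletons), -0.5)
  expect_error(weighted_modularity(
    weighted_graph(c("a", "b"), rbind(c(1, 2)), 0), singletons), "zero")

  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- 10
      pr <- t(utils::combn(n, 2))
      hit <- stats::runif(nrow(pr)) < 0.3
      if (sum(hit) < 2) next
      w <- weighted_graph(paste0("v", 1:n), pr[hit, , drop = FALSE],
                          stats::runif(sum(hit), 0.1, 2))
      memb <- sample(1:3, n, replace = TRUE)
      p <- tibble::tibble(node = paste0("v", 1:n), community = as.character(memb))
      ig <- as_igraph(w)
      ref <- igraph::modularity(ig, memb[match(igraph::V(ig)$name, w$nodes)],
                                weights = igraph::E(ig)$weight)
      expect_equal(weighted_modularity(w, p), ref, tolerance = 1e-10)
    }
  })
})

test_that("BGLL finds components, never decreases WQ, and matches the toy claim", {
  tri2 <- weighted_graph(paste0("n", 1:6),
                         rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)),
                         rep(1, 6))
  fit <- bgll(tri2, seed = 1)
  expect_equal(length(unique(fit$partition$community)), 2L)
  expect_equal(nmi(tibble::tibble(node = paste0("n", 1:6),
                                  community = rep(c("a", "b"), each = 3)),
                   fit$partition), 1)
  expect_equal(fit$details$wq, 0.5)

  # toy network: George lands with Ying, Hua, Pitt
  wt <- build_weighted_graph(g, "cns1")
  ft <- bgll(wt, seed = 1)
  memb <- stats::setNames(ft$partition$community, ft$partition$node)
  expect_equal(unname(memb["George"]), unname(memb["Ying"]))
  expect_equal(unname(memb["George"]), unname(memb["Hua"]))
  expect_equal(unname(memb["George"]), unname(memb["Pitt"]))
  expect_false(memb[["George"]] == memb[["Jones"]])

  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- 14
      pr <- t(utils::combn(n, 2))
      hit <- stats::runif(nrow(pr)) < 0.25
      if (sum(hit) < 3) next
      w <- weighted_graph(paste0("v", 1:n), pr[hit, , drop = FALSE],
                          stats::runif(sum(hit), 0.1, 2))
      f <- bgll(w, seed = rep)
      trace <- f$details$wq_trace
      # monotone non-decreasing trace of WQ over accepted moves
      expect_true(all(diff(trace) >= -1e-9))
      # final trace value equals the recomputed modularity of the partition
      expect_equal(trace[length(trace)],
                   weighted_modularity(w, f$partition), tolerance = 1e-9)
      # improves on the singleton start
      singles <- tibble::tibble(node = w$nodes,
                                community = as.character(seq_len(n)))
      expect_gte(f$details$wq, weighted_modularity(w, singles))
    }
  })
})

test_that("BGLL modularity is comparable to igraph's Louvain", {
  withr::with_seed(23, {
    bm <- generate_benchmark(benchmark_spec(mu = 0.2), seed = 9)
    w <- build_weighted_graph(bm$graph, "cns1")
    f <- bgll(w, seed = 2)
    ig <- as_igraph(w)
    ref <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight)
    expect_gte(f$details$wq, igraph::modularity(ref) - 0.03)
  })
})

test_that("K-medoids separates cliques and terminates on degenerate input", {
  # K = |V|: perfect self-partition
  w <- bridged_cliques()
  fit <- kmedoids(w, K = 8, seed = 1)
  expect_equal(length(unique(fit$partition$community)), 8L)

  cl <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)))
  wd <- weighted_graph(paste0("v", 1:8), cl, rep(1, nrow(cl)))
  hits <- vapply(1:100, function(s) {
    nmi(clique_truth(), kmedoids(wd, 2, seed = s)$partition) == 1
  }, logical(1))
  expect_gte(sum(hits), 95)

  # identical similarity rows: must terminate whatever the seed
  S <- matrix(1, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  for (s in 1:5) {
    f <- kmedoids(S, 2, seed = s)
    expect_equal(nrow(f$partition), 5L)
    expect_true(f$details$converged)
  }
  expect_error(kmedoids(S, 6), "between 1")
})

test_that("detect_communities drives all three algorithms end to end", {
  for (alg in c("bgll", "slpa")) {
    fit <- detect_communities(g, "cns1", alg, seed = 4)
    expect_s3_class(fit, "cns_communities")
    expect_equal(sort(fit$partition$node), sort(g$nodes))
    expect_false(anyNA(fit$partition$community))
  }
  fitk <- detect_communities(g, "cns1", "kmedoids", K = 2, seed = 4)
  expect_equal(nrow(fitk$partition), 7L)
  expect_error(detect_communities(g, "cns1", "kmedoids"), "K must be given")
  gl <- glance(detect_communities(g, "cns1", "bgll", seed = 1))
  expect_named(gl, c("algorithm", "measure", "n_communities", "wq", "converged"))
  expect_equal(gl$n_communities, 2L)
})

test_that("repeated runs are seed-reproducible and reduce to single runs", {
  r1 <- run_repeated(g, toy$truth, "cns1", "kmedoids", restarts = 1,
                     K = 2, seed = 10)
  expect_equal(nrow(r1$runs), 1L)
  fit_single <- kmedoids(build_weighted_graph(g, "cns1"), 2,
                         seed = withr::with_seed(10, sample.int(.Machine$integer.max - 1L, 1)))
  expect_equal(r1$runs$nmi, nmi(toy$truth, fit_single$partition))

  ra <- run_repeated(g, toy$truth, "cns1", "slpa", restarts = 5, seed = 3)
  rb <- run_repeated(g, toy$truth, "cns1", "slpa", restarts = 5, seed = 3)
  expect_equal(ra$runs, rb$runs)

  # deterministic per-restart seeds mean bgll repeats have zero nmi spread
  rd <- run_repeated(g, toy$truth, "cns1", "bgll", restarts = 3, seed = 3)
  expect_equal(rd$summary$sd_nmi, 0)
  expect_named(glance(rd),
               c("algorithm", "measure", "mean_nmi", "sd_nmi", "mean_f_measure",
                 "sd_f_measure", "mean_accuracy", "sd_accuracy", "mean_wq",
                 "n_runs"))
})
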