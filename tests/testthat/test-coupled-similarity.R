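toy <- toy_fixture()
g <- toy$graph

test_that("toy worked-example values are reproduced exactly", {
  expect_equal(intra_attribute_similarity(g, "country", "AU", "CN"), 6 / 11)
  expect_equal(icp(g, "topic", "DM", "country", "AU"), 1)
  expect_equal(icp(g, "topic", "ML", "country", "CN"), 1 / 3)
  expect_equal(inter_relative_similarity(g, "country", "topic", "AU", "CN"), 2 / 3)
  expect_equal(inter_attribute_similarity(g, "country", "AU", "CN"), 2 / 3)
  expect_equal(coupled_value_similarity(g, "country", "AU", "CN"), 6 / 11 * 2 / 3)
  expect_equal(attribute_structure_similarity(g, "country", "AU", "CN"), 0.5)
  expect_equal(attribute_structure_similarity(g, "topic", "DM", "DM"), 8 / 25)
  expect_equal(cns(g, "George", "Ying"), 158 / 385)
  expect_equal(round(cns(g, "George", "Ying"), 2), 0.41)
  expect_equal(round(cns(g, "George", "Jones"), 2), 0.29)
  expect_equal(cns(g, "George", "Jones"), 8 / 35 + 1 / 2 * 1 / 2 * 1 / 4)
  expect_gt(cns(g, "George", "Ying"), cns(g, "George", "Jones"))
})

test_that("intra-attribute similarity spans its theoretical range", {
  # singleton-vs-singleton value pair attains the 1/3 minimum
  g1 <- attributed_graph(NULL, data.frame(node = c("a", "b", "c"),
                                          f = c("x", "y", "z")))
  expect_equal(intra_attribute_similarity(g1, "f", "x", "y"), 1 / 3)
  expect_equal(intra_attribute_similarity(g, "topic", "DM", "DM"), 5 / 7)
  expect_error(intra_attribute_similarity(g, "topic", "nope", "DM"), "domain")
})

test_that("ICP respects boundary subsets and monotonicity", {
  expect_equal(icp(g, "topic", character(0), "country", "AU"), 0)
  expect_equal(icp(g, "topic", c("DM", "ML"), "country", "AU"), 1)
  expect_gte(icp(g, "topic", c("DM", "ML"), "country", "CN"),
             icp(g, "topic", "DM", "country", "CN"))
  expect_error(icp(g, "topic", "DM", "topic", "DM"), "must differ")
})

test_that("closed-form inter-relative similarity equals exhaustive subset minimisation", {
  expect_equal(inter_relative_similarity(g, "country", "topic", "AU", "US"), 0.5)
  withr::with_seed(202, {
    for (rep in 1:25) {
      rg <- random_attributed_graph(n_nodes = sample(4:12, 1), n_attr = 2,
                                    max_domain = 5)
      for (x in rg$domains[[1]]) for (y in rg$domains[[1]]) {
        expect_equal(inter_relative_similarity(rg, 1, 2, x, y),
                     oracle_inter_relative(rg, 1, 2, x, y),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("matched values give unit inter-attribute similarity under others-uniform", {
  for (v in g$domains[["country"]]) {
    expect_equal(inter_relative_similarity(g, "country", "topic", v, v), 1)
    expect_equal(inter_attribute_similarity(g, "country", v, v), 1)
  }
  # all-uniform weights sum to (M-1)/M over the other attributes
  expect_equal(inter_attribute_similarity(g, "country", "AU", "AU",
                                          alpha_scheme = "all-uniform"), 1 / 2)
  expect_equal(inter_attribute_similarity(g, "country", "AU", "CN",
                                          alpha_scheme = "all-uniform"), 1 / 3)
})

test_that("single-attribute graphs fall back to unit inter similarity", {
  g1 <- attributed_graph(data.frame(from = "a", to = "b"),
                         data.frame(node = c("a", "b"), f = c("x", "y")))
  expect_message(v <- inter_attribute_similarity(g1, "f", "x", "y"),
                 "single-attribute")
  expect_equal(v, 1)
})

test_that("structure similarity counts ordered cross pairs", {
  expect_equal(attribute_structure_similarity(g, "country", "AU", "US"), 1 / 4)
  # no cross edges between the two topics' singleton groups elsewhere
  g2 <- attributed_graph(data.frame(from = "a", to = "b"),
                         data.frame(node = c("a", "b", "c"),
                                    f = c("x", "x", "y")))
  expect_equal(attribute_structure_similarity(g2, "f", "x", "y"), 0)
  # empty-edge graph: zero everywhere
  g0 <- attributed_graph(NULL, data.frame(node = c("a", "b"), f = c("x", "y")))
  expect_equal(attribute_structure_similarity(g0, "f", "x", "y"), 0)
})

test_that("node-level CAS and CNS are symmetric and correctly combined", {
  expect_equal(cas(g, "George", "Ying"), 5 / 7 + 4 / 11)
  for (i in g$nodes) for (j in g$nodes) {
    expect_equal(cas(g, i, j), cas(g, j, i))
    for (v in c("cns1", "cns2", "cns3", "cns4")) {
      expect_equal(cns(g, i, j, variant = v), cns(g, j, i, variant = v))
    }
  }
  # self-similarity uses the same formulas, not a forced maximum
  expect_lt(cas(g, "George", "George"), 2)
  # variant formulas at one pair, from the per-attribute components
  comp <- function(m, x, y) c(ia = intra_attribute_similarity(g, m, x, y),
                              ie = inter_attribute_similarity(g, m, x, y),
                              as = attribute_structure_similarity(g, m, x, y))
  t1 <- comp("topic", "DM", "DM"); c1 <- comp("country", "AU", "CN")
  expect_equal(cns(g, "George", "Ying", "cns2"),
               (t1["ia"] + t1["ie"]) * t1["as"] + (c1["ia"] + c1["ie"]) * c1["as"],
               ignore_attr = TRUE)
  expect_equal(cns(g, "George", "Ying", "cns3"),
               t1["ia"] * t1["ie"] + t1["as"] + c1["ia"] * c1["ie"] + c1["as"],
               ignore_attr = TRUE)
  expect_equal(cns(g, "George", "Ying", "cns4"),
               sum(t1) + sum(c1), ignore_attr = TRUE)
})

test_that("baseline similarities match their definitions on the toy graph", {
  expect_equal(baseline_similarity(g, "George", "Ying", "smc"), 1 / 2)
  expect_equal(baseline_similarity(g, "George", "Pitt", "adjacency"), 0)
  expect_equal(baseline_similarity(g, "George", "Ying", "adjacency"), 1)
  expect_equal(baseline_similarity(g, "David", "George", "cosine"),
               1 / sqrt(2 * 2))  # shared neighbour Jones
  expect_equal(baseline_similarity(g, "David", "George", "jaccard"), 1 / 3)
  # identical neighbourhoods give jaccard 1
  g3 <- attributed_graph(data.frame(from = c("a", "b"), to = c("c", "c")),
                         data.frame(node = c("a", "b", "c"), f = c("x", "x", "y")))
  expect_equal(baseline_similarity(g3, "a", "b", "jaccard"), 1)
  # isolated node convention
  g4 <- attributed_graph(data.frame(from = "a", to = "b"),
                         data.frame(node = c("a", "b", "c"), f = c("x", "x", "y")))
  expect_equal(baseline_similarity(g4, "a", "c", "cosine"), 0)
  expect_equal(baseline_similarity(g4, "a", "c", "jaccard"), 0)
})

test_that("value-pair tables are symmetric, bounded and consistent", {
  for (a in c("topic", "country")) {
    vt <- value_pair_table(g, a)
    expect_true(all(vt$delta_intra >= 1 / 3 & vt$delta_intra < 1))
    expect_true(all(vt$delta_inter >= 0 & vt$delta_inter <= 1))
    expect_true(all(vt$delta_struct >= 0 & vt$delta_struct <= 1))
    expect_equal(vt$delta_attr, vt$delta_intra * vt$delta_inter)
    for (r in seq_len(nrow(vt))) {
      expect_equal(vt$delta_intra[r],
                   intra_attribute_similarity(g, a, vt$x[r], vt$y[r]))
      expect_equal(vt$delta_inter[r],
                   inter_attribute_similarity(g, a, vt$x[r], vt$y[r]))
      expect_equal(vt$delta_struct[r],
                   attribute_structure_similarity(g, a, vt$x[r], vt$y[r]))
    }
    # matched-value inter similarity is 1
    diag_rows <- vt[vt$x == vt$y, ]
    expect_equal(diag_rows$delta_inter, rep(1, nrow(diag_rows)))
  }
})

test_that("similarity matrices agree with pairwise operations", {
  S <- similarity_matrix(g, "cns1")
  expect_equal(sum(S > 0), 16)  # 8 undirected edges, both triangles
  for (e in seq_len(n_edges(g))) {
    i <- g$nodes[g$edges[e, 1]]; j <- g$nodes[g$edges[e, 2]]
    expect_equal(S[i, j], cns(g, i, j))
    expect_equal(S[i, j], S[j, i])
  }
  A <- similarity_matrix(g, "adjacency")
  expect_equal(unname(A["George", "Ying"]), 1)
  expect_equal(sum(A) / 2, 8)
  for (msr in c("cosine", "jaccard", "smc", "cas")) {
    Sm <- similarity_matrix(g, msr)
    expect_equal(Sm, t(Sm))
    for (pair in list(c("David", "George"), c("George", "Ying"))) {
      expected <- if (msr == "cas") cas(g, pair[1], pair[2])
                  else baseline_similarity(g, pair[1], pair[2], msr)
      expect_equal(Sm[pair[1], pair[2]], expected)
    }
  }
  # full mode fills non-adjacent CNS pairs too
  Sf <- similarity_matrix(g, "cns1", full = TRUE)
  expect_equal(Sf["George", "Ying"], S["George", "Ying"])
  expect_gte(Sf["David", "Hua"], 0)
  # empty-edge graph gives an all-zero CNS matrix
  g0 <- attributed_graph(NULL, data.frame(node = c("a", "b"),
                                          f = c("x", "y"), h = c("u", "u")))
  expect_equal(sum(similarity_matrix(g0, "cns1")), 0)
})

test_that("CNS1 never exceeds CAS and node relabelling permutes matrices", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      rg <- random_attributed_graph(n_nodes = 9, n_attr = 3)
      S_cns <- similarity_matrix(rg, "cns1", full = TRUE)
      S_cas <- similarity_matrix(rg, "cas", full = TRUE)
      expect_true(all(S_cns <= S_cas + 1e-12))

      perm <- sample(n_nodes(rg))
      at2 <- node_attributes(rg)[perm, ]
      g2 <- attributed_graph(edge_table(rg), at2)
      S2 <- similarity_matrix(g2, "cns1", full = TRUE)
      expect_equal(S2[rg$nodes, rg$nodes], S_cns[rg$nodes, rg$nodes])
    }
  })
})

test_that("tidy node_similarity output matches the matrix", {
  ns <- node_similarity(g, "cns1")
  expect_equal(nrow(ns), 8L)
  S <- similarity_matrix(g, "cns1")
  expect_equal(ns$similarity, S[cbind(ns$from, ns$to)])
  ns_all <- node_similarity(g, "smc", pairs = "all")
  expect_equal(nrow(ns_all), choose(7, 2))
})
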