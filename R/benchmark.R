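#' The seven-author toy network
#'
#' A small co-authoring network of seven authors with two categorical
#' attributes (research `topic` and `country`), used throughout the
#' documentation and tests as a fully worked example: it is small enough that
#' every coupled-similarity quantity can be checked by hand. The ground truth
#' splits the authors into two communities, with George belonging to the
#' Ying/Hua/Pitt group — the assignment that attribute-aware similarity
#' recovers but structure alone cannot.
#'
#' @return A list with components `graph` (an [attributed_graph()], 7 nodes,
#'   8 edges, 2 attributes) and `truth` (the ground-truth partition tibble).
#' @examples
#' toy <- toy_fixture()
#' toy$graph
#' @export
toy_fixture <- function() {
  attrs <- tibble::tibble(
    node = c("David", "Jia", "Jones", "George", "Ying", "Hua", "Pitt"),
    topic = c("ML", "DM", "DM", "DM", "DM", "ML", "DM"),
    country = c("US", "CN", "US", "AU", "CN", "CN", "AU")
  )
  edges <- tibble::tribble(
    ~from, ~to,
    "David", "Jia",
    "David", "Jones",
    "Jia", "Jones",
    "Jones", "George",
    "George", "Ying",
    "Ying", "Hua",
    "Ying", "Pitt",
    "Hua", "Pitt"
  )
  truth <- tibble::tibble(
    node = attrs$node,
    community = c("C1", "C1", "C1", "C2", "C2", "C2", "C2")
  )
  list(graph = attributed_graph(edges, attrs), truth = truth)
}

#' Specification of a synthetic attributed benchmark network
#'
#' Bundles and validates the parameters of the planted-partition generator:
#' node count `n`, target mean degree `avg_degree`, degree cap `max_degree`,
#' community size range `[min_comm, max_comm]`, mixing parameter `mu` (the
#' probability that an edge endpoint leads outside its community), the
#' attribute assignment rules, and the noise level `nl` for rule 3.
#'
#' @param n Number of nodes.
#' @param avg_degree Target mean degree.
#' @param max_degree Maximum degree (`avg_degree <= max_degree < n`).
#' @param min_comm,max_comm Minimum / maximum community size.
#' @param mu Mixing parameter in `[0, 1]`.
#' @param rules Character vector of attribute rules, each `"rule1"`, `"rule2"`
#'   or `"rule3"`; one attribute is generated per entry. Default is the
#'   three-attribute trio `rule1, rule2, rule3`.
#' @param nl Noise level in `[0, 1]` for rule-3 attributes.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n = 100L, avg_degree = 5, max_degree = 10L,
                           min_comm = 10L, max_comm = 30L, mu = 0.1,
                           rules = c("rule1", "rule2", "rule3"), nl = 0.3) {
  n <- as.integer(n)
  stopifnot(n >= 2L, mu >= 0, mu <= 1, nl >= 0, nl <= 1)
  if (min_comm > max_comm) stop("min_comm exceeds max_comm", call. = FALSE)
  if (min_comm > n) stop("min_comm exceeds the node count", call. = FALSE)
  if (avg_degree > max_degree) stop("avg_degree exceeds max_degree", call. = FALSE)
  if (max_degree >= n) stop("max_degree must be below the node count", call. = FALSE)
  rules <- match.arg(rules, c("rule1", "rule2", "rule3"), several.ok = TRUE)
  structure(list(n = n, avg_degree = avg_degree, max_degree = as.integer(max_degree),
                 min_comm = as.integer(min_comm), max_comm = as.integer(max_comm),
                 mu = mu, rules = rules, nl = nl),
            class = "benchmark_spec")
}

# safe sample: never the 1:n expansion on a length-one vector
resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

# community sizes in [min_comm, max_comm] summing exactly to n
sample_community_sizes <- function(n, min_comm, max_comm) {
  sizes <- integer(0)
  left <- n
  while (left >= min_comm) {
    s <- resample(seq(min_comm, min(max_comm, left)), 1L)
    sizes <- c(sizes, s)
    left <- left - s
  }
  while (left > 0L) {                        # spread the remainder
    room <- which(sizes < max_comm)
    if (!length(room)) stop("cannot fit ", n, " nodes into communities of size [",
                            min_comm, ", ", max_comm, "]", call. = FALSE)
    take <- room[seq_len(min(left, length(room)))]
    sizes[take] <- sizes[take] + 1L
    left <- left - length(take)
  }
  sizes
}

# target degrees: discrete truncated power law (exponent 2) on [k0, max_degree],
# lower cutoff k0 tuned (with randomised rounding between adjacent cutoffs) so
# the expected mean matches avg_degree
sample_degrees <- function(n, avg_degree, max_degree) {
  mean_for <- function(k0) {
    ks <- k0:max_degree
    p <- ks^(-2)
    sum(ks * p) / sum(p)
  }
  means <- vapply(1:max_degree, mean_for, numeric(1))
  if (avg_degree <= means[1L]) {
    k0_lo <- k0_hi <- 1L; frac <- 0
  } else if (avg_degree >= means[max_degree]) {
    k0_lo <- k0_hi <- max_degree; frac <- 0
  } else {
    k0_lo <- max(which(means <= avg_degree))
    k0_hi <- k0_lo + 1L
    frac <- (avg_degree - means[k0_lo]) / (means[k0_hi] - means[k0_lo])
  }
  draw_one <- function(k0) {
    ks <- k0:max_degree
    p <- ks^(-2)
    resample(ks, 1L, prob = p)
  }
  cutoffs <- ifelse(stats::runif(n) < frac, k0_hi, k0_lo)
  vapply(cutoffs, draw_one, numeric(1))
}

#' Generate the planted community structure of a benchmark network
#'
#' Samples an undirected simple graph with planted communities in the style of
#' the LFR benchmarks: community sizes are drawn uniformly from
#' `[min_comm, max_comm]` (summing to `n`), per-node target degrees from a
#' truncated power law with mean `avg_degree` capped at `max_degree`, each
#' node's degree is split into an external part (Binomial with probability
#' `mu`) and an internal part, and edges are realised by within-community and
#' cross-community Chung-Lu wiring so expected degrees match the targets. At
#' `mu = 0` no cross-community edge exists.
#'
#' @param spec A [benchmark_spec()].
#' @param seed Optional integer seed.
#' @return A list: `edges` (tibble `from`, `to` over nodes `"n1".."nN"`),
#'   `truth` (ground-truth partition tibble), `membership` (integer vector).
#' @export
generate_structure <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  run <- function() generate_structure_run(spec)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

generate_structure_run <- function(spec) {
  n <- spec$n
  sizes <- sample_community_sizes(n, spec$min_comm, spec$max_comm)
  membership <- sample(rep(seq_along(sizes), sizes))
  deg <- sample_degrees(n, spec$avg_degree, spec$max_degree)

  d_ext <- stats::rbinom(n, deg, spec$mu)
  d_int <- deg - d_ext
  # internal degree cannot exceed community size - 1
  for (i in seq_len(n)) {
    cap <- sizes[membership[i]] - 1L
    if (d_int[i] > cap) {
      if (spec$mu > 0) d_ext[i] <- d_ext[i] + (d_int[i] - cap)
      d_int[i] <- cap
    }
  }

  from <- integer(0); to <- integer(0)
  has_edge <- new.env(hash = TRUE)
  add_edges <- function(u, v) {
    for (k in seq_along(u)) assign(paste(u[k], v[k]), TRUE, envir = has_edge)
    from <<- c(from, u); to <<- c(to, v)
  }
  # within-community Chung-Lu wiring
  for (c in seq_along(sizes)) {
    members <- which(membership == c)
    s_tot <- sum(d_int[members])
    if (s_tot <= 0 || length(members) < 2L) next
    pr <- utils::combn(members, 2L)
    p <- pmin(1, d_int[pr[1L, ]] * d_int[pr[2L, ]] / s_tot)
    hit <- stats::runif(ncol(pr)) < p
    add_edges(pr[1L, hit], pr[2L, hit])
  }
  # cross-community Chung-Lu wiring
  s_ext <- sum(d_ext)
  if (s_ext > 0) {
    ext_nodes <- which(d_ext > 0)
    if (length(ext_nodes) >= 2L) {
      pr <- utils::combn(ext_nodes, 2L)
      diff_comm <- membership[pr[1L, ]] != membership[pr[2L, ]]
      pr <- pr[, diff_comm, drop = FALSE]
      if (ncol(pr)) {
        # renormalise per community: only stubs outside a node's own community
        # are eligible partners
        s_ext_c <- vapply(seq_along(sizes),
                          function(c) sum(d_ext[membership == c]), numeric(1))
        den <- sqrt((s_ext - s_ext_c[membership[pr[1L, ]]]) *
                      (s_ext - s_ext_c[membership[pr[2L, ]]]))
        p <- pmin(1, d_ext[pr[1L, ]] * d_ext[pr[2L, ]] / pmax(den, 1))
        hit <- stats::runif(ncol(pr)) < p
        add_edges(pr[1L, hit], pr[2L, hit])
      }
    }
  }
  # repair rounds: Chung-Lu leaves hubs in small dense communities short of
  # their target degree; pair up deficit stubs (internal within community,
  # external across communities) on non-adjacent pairs until targets are met
  # or no legal pair remains
  realized <- tabulate(c(from, to), nbins = n)
  realized_int <- tabulate(c(from[membership[from] == membership[to]],
                             to[membership[from] == membership[to]]), nbins = n)
  def_int <- pmax(d_int - realized_int, 0L)
  def_ext <- pmax(d_ext - (realized - realized_int), 0L)
  # global budget: only add as many edges as the overall degree shortfall
  # (per-node surpluses from the random wiring offset per-node deficits)
  shortfall <- max(0, round((sum(deg) - sum(realized)) / 2))
  budget_int <- round(shortfall * (1 - spec$mu))
  budget_ext <- shortfall - budget_int
  pairable <- function(u, v) {
    u2 <- min(u, v); v2 <- max(u, v)
    u2 != v2 && !exists(paste(u2, v2), envir = has_edge, inherits = FALSE)
  }
  for (c in sample.int(length(sizes))) {
    for (tries in seq_len(4L * sizes[c])) {
      if (budget_int <= 0L) break
      open <- which(membership == c & def_int > 0L)
      if (length(open) < 2L) break
      uv <- resample(open, 2L)
      if (pairable(uv[1L], uv[2L])) {
        add_edges(min(uv), max(uv))
        def_int[uv] <- def_int[uv] - 1L
        budget_int <- budget_int - 1L
      }
    }
  }
  if (spec$mu > 0) {
    for (tries in seq_len(4L * n)) {
      if (budget_ext <= 0L) break
      open <- which(def_ext > 0L)
      if (length(open) < 2L) break
      uv <- resample(open, 2L)
      if (membership[uv[1L]] != membership[uv[2L]] && pairable(uv[1L], uv[2L])) {
        add_edges(min(uv), max(uv))
        def_ext[uv] <- def_ext[uv] - 1L
        budget_ext <- budget_ext - 1L
      }
    }
  }

  nodes <- paste0("n", seq_len(n))
  list(
    edges = tibble::tibble(from = nodes[from], to = nodes[to]),
    truth = tibble::tibble(node = nodes, community = paste0("c", membership)),
    membership = membership
  )
}

#' Assign a categorical attribute column over a planted partition
#'
#' Three generation rules tie an attribute to the planted communities with
#' decreasing fidelity:
#' \describe{
#'   \item{`rule1`}{every node gets its community's own identifier — a fully
#'     informative attribute;}
#'   \item{`rule2`}{every node gets a value drawn uniformly from a domain the
#'     size of the number of communities — an uninformative attribute;}
#'   \item{`rule3`}{as rule 1, then in each community a fraction `nl` of the
#'     nodes (`round(nl * size)` of them) is replaced by a random value
#'     different from the community's own — a noisy informative attribute.}
#' }
#'
#' @param truth Ground-truth partition (see [as_partition()]).
#' @param rule `"rule1"`, `"rule2"` or `"rule3"`.
#' @param nl Noise level in `[0, 1]` (rule 3 only).
#' @param seed Optional integer seed.
#' @param domain_size Domain size for rule 2; defaults to the number of
#'   communities.
#' @return A character vector of attribute values aligned with `truth$node`.
#' @export
assign_attributes <- function(truth, rule = c("rule1", "rule2", "rule3"),
                              nl = 0.3, seed = NULL, domain_size = NULL) {
  rule <- match.arg(rule)
  if (nl < 0 || nl > 1) stop("nl must lie in [0, 1]", call. = FALSE)
  p <- as_partition(truth)
  comms <- unique(p$community)
  run <- function() {
    if (rule == "rule2") {
      k <- domain_size %||% length(comms)
      return(paste0("v", sample.int(k, nrow(p), replace = TRUE)))
    }
    vals <- p$community
    if (rule == "rule3" && nl > 0) {
      if (length(comms) < 2L) {
        warning("rule3 needs at least two communities to draw noise values; ",
                "returning the rule1 assignment", call. = FALSE)
        return(vals)
      }
      for (c in comms) {
        members <- which(p$community == c)
        n_noise <- round(nl * length(members))
        if (n_noise > 0L) {
          noisy <- resample(members, n_noise)
          others <- setdiff(comms, c)
          vals[noisy] <- resample(others, n_noise, replace = TRUE)
        }
      }
    }
    vals
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a complete synthetic attributed benchmark network
#'
#' Composes [generate_structure()] with one [assign_attributes()] column per
#' configured rule. The default spec reproduces the standard benchmark
#' conditions: 100 nodes, mean degree 5 capped at 10, communities of 10-30
#' nodes, and the attribute trio (rule 1, rule 2, rule 3 at noise level 0.3).
#'
#' @inheritParams generate_structure
#' @return A list: `graph` (an [attributed_graph()] with attributes
#'   `attr1`, `attr2`, ...), `truth` (ground-truth partition tibble), and
#'   `spec`.
#' @examples
#' bm <- generate_benchmark(benchmark_spec(mu = 0.1), seed = 42)
#' bm$graph
#' @export
generate_benchmark <- function(spec = benchmark_spec(), seed = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  run <- function() {
    st <- generate_structure_run(spec)
    attrs <- tibble::tibble(node = st$truth$node)
    for (i in seq_along(spec$rules)) {
      attrs[[paste0("attr", i)]] <-
        assign_attributes(st$truth, spec$rules[i], nl = spec$nl)
    }
    list(graph = attributed_graph(st$edges, attrs), truth = st$truth, spec = spec)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Realized structural statistics of a generated network
#'
#' Diagnostics for generator calibration: the realized mean degree and the
#' realized mixing fraction (mean over non-isolated nodes of the share of
#' their edges that leave their community).
#'
#' @param g An [attributed_graph()].
#' @param truth Ground-truth partition.
#' @return A one-row tibble `mean_degree`, `mixing`.
#' @export
structure_stats <- function(g, truth) {
  memb <- membership_vector(g, truth)
  deg <- lengths(adjacency_list(g))
  ext <- numeric(n_nodes(g))
  if (nrow(g$edges)) {
    cu <- memb[g$edges[, 1L]]; cv <- memb[g$edges[, 2L]]
    cross <- cu != cv
    for (e in which(cross)) {
      ext[g$edges[e, 1L]] <- ext[g$edges[e, 1L]] + 1
      ext[g$edges[e, 2L]] <- ext[g$edges[e, 2L]] + 1
    }
  }
  ok <- deg > 0
  tibble::tibble(
    mean_degree = mean(deg),
    mixing = if (any(ok)) mean(ext[ok] / deg[ok]) else NA_real_
  )
}
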