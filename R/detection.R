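# modal label of a multiset, ties broken uniformly at random
modal_label <- function(labels) {
  tab <- tabulate(labels)
  best <- which(tab == max(tab))
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' Weight a graph's edges by a node similarity
#'
#' Converts an attributed graph into a weighted graph: each existing edge gets
#' the similarity of its endpoints as weight, and non-adjacent pairs carry no
#' weight. Edges whose endpoint similarity is exactly zero are kept with
#' weight zero.
#'
#' @param g An [attributed_graph()].
#' @param similarity Either a measure name (see [similarity_matrix()]) or a
#'   precomputed similarity matrix over `g`'s nodes.
#' @param alpha_scheme Passed to [similarity_matrix()] when `similarity` is a
#'   measure name.
#' @return A [weighted_graph()].
#' @examples
#' g <- toy_fixture()$graph
#' w <- build_weighted_graph(g, "cns1")
#' @export
build_weighted_graph <- function(g, similarity = "cns1",
                                 alpha_scheme = c("others-uniform", "all-uniform")) {
  alpha_scheme <- match.arg(alpha_scheme)
  S <- if (is.character(similarity)) {
    similarity_matrix(g, similarity, alpha_scheme, full = FALSE)
  } else {
    stopifnot(is.matrix(similarity), nrow(similarity) == n_nodes(g))
    similarity
  }
  wts <- if (nrow(g$edges)) S[g$edges] else numeric(0)
  weighted_graph(g$nodes, g$edges, wts)
}

#' Speaker-listener label propagation (SLPA) on a weighted graph
#'
#' Every node starts with a unique label and a memory containing it. At each
#' iteration nodes are visited in random order; the visited node (listener)
#' receives one label from every neighbour (the speaker sends the most
#' frequent label in its memory, ties uniform), scores each received label by
#' the sum of the sending edges' weights, and appends the best-scoring label
#' (ties uniform) to its memory. After the final iteration every node adopts
#' the most frequent label in its memory, inducing a disjoint partition.
#'
#' @param w A [weighted_graph()].
#' @param iterations Number of propagation iterations (default 20); memory
#'   length is `iterations + 1`.
#' @param seed Optional integer seed for all randomness (visit order and tie
#'   breaks).
#' @return An object of class `cns_communities` (see [detect_communities()]).
#' @export
slpa <- function(w, iterations = 20L, seed = NULL) {
  stopifnot(inherits(w, "weighted_graph"))
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  run <- function() slpa_run(w, iterations)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new_communities(w$nodes, res$labels, algorithm = "slpa", seed = seed,
                  details = list(iterations = iterations))
}

slpa_run <- function(w, iterations) {
  n <- length(w$nodes)
  adj <- vector("list", n); wadj <- vector("list", n)
  for (i in seq_len(n)) { adj[[i]] <- integer(0); wadj[[i]] <- numeric(0) }
  if (nrow(w$edges)) {
    for (e in seq_len(nrow(w$edges))) {
      u <- w$edges[e, 1L]; v <- w$edges[e, 2L]
      adj[[u]] <- c(adj[[u]], v); wadj[[u]] <- c(wadj[[u]], w$weights[e])
      adj[[v]] <- c(adj[[v]], u); wadj[[v]] <- c(wadj[[v]], w$weights[e])
    }
  }
  mem <- matrix(0L, n, iterations + 1L)
  mem[, 1L] <- seq_len(n)
  len <- rep(1L, n)
  for (t in seq_len(iterations)) {
    for (i in sample.int(n)) {
      nb <- adj[[i]]
      if (!length(nb)) {                    # isolated: reinforce own memory
        mem[i, len[i] + 1L] <- modal_label(mem[i, seq_len(len[i])])
        len[i] <- len[i] + 1L
        next
      }
      sent <- vapply(nb, function(j) modal_label(mem[j, seq_len(len[j])]), integer(1))
      score <- rowsum(wadj[[i]], sent)
      lab <- as.integer(rownames(score))
      best <- lab[score[, 1L] == max(score[, 1L])]
      pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
      mem[i, len[i] + 1L] <- pick
      len[i] <- len[i] + 1L
    }
  }
  labels <- vapply(seq_len(n), function(i) modal_label(mem[i, seq_len(len[i])]),
                   integer(1))
  list(labels = labels)
}

#' Weighted modularity of a partition
#'
#' Quality of a partition of a weighted graph: over ordered node pairs,
#' `WQ = (1/mw) * sum_ij [W(i,j) - s_i s_j / mw] * 1(c_i = c_j)` with `s_i`
#' the node strengths and `mw` the ordered-pair weight total (twice the sum of
#' edge weights). The all-in-one-community partition scores exactly 0.
#'
#' @param w A [weighted_graph()] with positive total weight.
#' @param partition A partition of `w`'s nodes (see [as_partition()]).
#' @return A number in `[-1, 1]`.
#' @export
weighted_modularity <- function(w, partition) {
  mw <- total_weight(w)
  if (mw <= 0) stop("weighted modularity undefined: total edge weight is zero",
                    call. = FALSE)
  memb <- membership_vector(list(nodes = w$nodes), partition)
  s <- node_strength(w)
  inw <- numeric(max(memb))                 # ordered intra-community weight
  if (nrow(w$edges)) {
    cu <- memb[w$edges[, 1L]]; cv <- memb[w$edges[, 2L]]
    same <- cu == cv
    if (any(same)) {
      add <- rowsum(2 * w$weights[same], cu[same])
      inw[as.integer(rownames(add))] <- add[, 1L]
    }
  }
  sc <- as.numeric(rowsum(s, memb))
  sum(inw / mw - (sc / mw)^2)
}

#' Weighted-modularity Louvain optimisation (BGLL)
#'
#' Two-phase greedy optimisation of the weighted modularity
#' ([weighted_modularity()]). Phase one starts from singleton communities and
#' repeatedly moves each node (in a seeded random sweep order) to the
#' neighbouring community with the largest positive modularity gain until no
#' move improves. Phase two aggregates communities into super-nodes (summed
#' inter-community weights; intra-community weight as a self-loop) and the
#' phases repeat until the modularity stops increasing. The modularity value
#' after every accepted move is recorded; the trace is non-decreasing by
#' construction.
#'
#' @inheritParams weighted_modularity
#' @param seed Optional integer seed controlling sweep order.
#' @return A `cns_communities` object; `$details$wq_trace` holds the
#'   modularity after each accepted move and `$details$wq` the final value.
#' @export
bgll <- function(w, seed = NULL) {
  stopifnot(inherits(w, "weighted_graph"))
  mw <- total_weight(w)
  if (mw <= 0) stop("BGLL undefined: total edge weight is zero", call. = FALSE)
  run <- function() bgll_run(w)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new_communities(w$nodes, res$membership, algorithm = "bgll", seed = seed,
                  details = list(wq = res$wq, wq_trace = res$trace,
                                 levels = res$levels))
}

bgll_run <- function(w) {
  mw <- total_weight(w)
  # working multigraph representation: edge index matrix, weights, self-loops
  n <- length(w$nodes)
  edges <- w$edges
  weights <- w$weights
  self <- numeric(n)                        # ordered-pair self-loop weight
  global_memb <- seq_len(n)                 # membership of original nodes
  trace <- numeric(0)
  eps <- 1e-12

  repeat {
    nn <- max(global_memb)
    # adjacency (neighbour -> summed weight) for current coarse graph
    nbr <- vector("list", nn)
    for (i in seq_len(nn)) nbr[[i]] <- numeric(0)
    if (nrow(edges)) {
      for (e in seq_len(nrow(edges))) {
        u <- edges[e, 1L]; v <- edges[e, 2L]; wt <- weights[e]
        cu <- nbr[[u]][as.character(v)]
        nbr[[u]][as.character(v)] <- if (is.na(cu)) wt else cu + wt
        cv <- nbr[[v]][as.character(u)]
        nbr[[v]][as.character(u)] <- if (is.na(cv)) wt else cv + wt
      }
    }
    strength <- self
    for (i in seq_len(nn)) strength[i] <- strength[i] + sum(nbr[[i]])

    comm <- seq_len(nn)
    sc <- strength                          # community strength totals
    inw <- self                             # community ordered intra weight
    Q <- sum(inw / mw - (sc / mw)^2)
    if (!length(trace)) trace <- Q

    improved_level <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(nn)) {
        ci <- comm[i]
        nb <- nbr[[i]]
        if (!length(nb)) next
        nb_comm <- comm[as.integer(names(nb))]
        k_ic <- rowsum(unname(nb), nb_comm)  # weight from i to each community
        cand <- as.integer(rownames(k_ic))
        k_ic <- k_ic[, 1L]
        k_own <- if (ci %in% cand) k_ic[match(ci, cand)] else 0
        # detach i from its community
        sc[ci] <- sc[ci] - strength[i]
        inw[ci] <- inw[ci] - 2 * k_own - self[i]
        # gain of inserting i into community c (relative, common terms dropped):
        # 2*k_ic/mw - 2*strength_i*sc_c/mw^2
        gain <- 2 * k_ic / mw - 2 * strength[i] * sc[cand] / mw^2
        gain_stay <- 2 * k_own / mw - 2 * strength[i] * sc[ci] / mw^2
        gain <- unname(gain); gain_stay <- unname(gain_stay)
        best <- which.max(gain)
        if (gain[best] > gain_stay + eps) {
          cnew <- cand[best]
          comm[i] <- cnew
          sc[cnew] <- sc[cnew] + strength[i]
          inw[cnew] <- inw[cnew] + 2 * k_ic[best] + self[i]
          Q <- Q + (gain[best] - gain_stay)
          trace <- c(trace, Q)
          moved <- TRUE
          improved_level <- TRUE
        } else {                            # reattach where it was
          comm[i] <- ci
          sc[ci] <- sc[ci] + strength[i]
          inw[ci] <- inw[ci] + 2 * k_own + self[i]
        }
      }
      if (!moved) break
    }

    if (!improved_level) break

    # aggregate: communities become nodes
    new_ids <- match(comm, sort(unique(comm)))
    global_memb <- new_ids[global_memb]
    nn2 <- max(new_ids)
    self2 <- numeric(nn2)
    for (i in seq_len(nn)) self2[new_ids[i]] <- self2[new_ids[i]] + self[i]
    if (nrow(edges)) {
      cu <- new_ids[edges[, 1L]]; cv <- new_ids[edges[, 2L]]
      same <- cu == cv
      if (any(same)) {
        add <- rowsum(2 * weights[same], cu[same])
        self2[as.integer(rownames(add))] <- self2[as.integer(rownames(add))] + add[, 1L]
      }
      keep <- !same
      if (any(keep)) {
        a <- pmin(cu[keep], cv[keep]); b <- pmax(cu[keep], cv[keep])
        agg <- rowsum(weights[keep], paste(a, b))
        key <- do.call(rbind, strsplit(rownames(agg), " "))
        edges <- cbind(as.integer(key[, 1L]), as.integer(key[, 2L]))
        weights <- agg[, 1L]
      } else {
        edges <- matrix(integer(0), ncol = 2L); weights <- numeric(0)
      }
    }
    self <- self2
    if (nn2 == nn) break                    # no coarsening possible
  }

  list(membership = global_memb, wq = unname(trace[length(trace)]),
       trace = unname(trace), levels = NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Similarity-based K-medoids clustering
#'
#' Partitions nodes from a similarity matrix (typically the edge-weight matrix,
#' where disconnected pairs have similarity 0): `K` distinct initial medoids
#' are drawn uniformly at random, every node is assigned to the medoid it is
#' most similar to (ties to the lowest medoid index; a node with zero
#' similarity to all medoids is attached to a random medoid), each medoid is
#' then replaced by the cluster member whose average similarity to the cluster
#' is maximal, and assignment/update alternate until the medoid set is stable.
#' A medoid always belongs to its own cluster.
#'
#' @param s A symmetric similarity matrix (or a [weighted_graph()], whose
#'   dense weight matrix is used).
#' @param K Number of clusters, `K <=` number of nodes.
#' @param seed Optional integer seed (initial medoids and random tie breaks).
#' @param max_iter Iteration cap (convergence is flagged in the result).
#' @return A `cns_communities` object; `$details$converged` reports whether the
#'   medoids stabilised within `max_iter`.
#' @export
kmedoids <- function(s, K, seed = NULL, max_iter = 100L) {
  if (inherits(s, "weighted_graph")) {
    n <- length(s$nodes)
    S <- matrix(0, n, n, dimnames = list(s$nodes, s$nodes))
    if (nrow(s$edges)) {
      S[s$edges] <- s$weights
      S[s$edges[, c(2L, 1L), drop = FALSE]] <- s$weights
    }
    s <- S
  }
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  n <- nrow(s)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("K must be between 1 and the number of nodes", call. = FALSE)
  nodes <- rownames(s) %||% as.character(seq_len(n))
  run <- function() kmedoids_run(s, K, max_iter)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new_communities(nodes, res$labels, algorithm = "kmedoids", seed = seed,
                  details = list(K = K, iterations = res$iterations,
                                 converged = res$converged))
}

kmedoids_run <- function(s, K, max_iter) {
  n <- nrow(s)
  medoids <- sort(sample.int(n, K))
  converged <- FALSE
  iter <- 0L
  labels <- integer(n)
  repeat {
    iter <- iter + 1L
    sim_to_med <- s[, medoids, drop = FALSE]
    labels <- max.col(sim_to_med, ties.method = "first")  # lowest medoid on ties
    best <- sim_to_med[cbind(seq_len(n), labels)]
    zero <- which(best <= 0)
    if (length(zero)) labels[zero] <- sample.int(K, length(zero), replace = TRUE)
    labels[medoids] <- seq_len(K)           # a medoid anchors its own cluster
    new_medoids <- medoids
    for (k in seq_len(K)) {
      members <- which(labels == k)
      if (!length(members)) next            # empty cluster keeps its medoid
      avg <- colMeans(s[members, members, drop = FALSE])
      new_medoids[k] <- members[which.max(avg)]
    }
    new_medoids <- sort(new_medoids)
    if (identical(new_medoids, medoids)) { converged <- TRUE; break }
    medoids <- new_medoids
    if (iter >= max_iter) break
  }
  list(labels = labels, iterations = iter, converged = converged)
}

# ---- result container and high-level drivers --------------------------------

new_communities <- function(nodes, labels, algorithm, seed = NULL,
                            measure = NULL, details = list()) {
  labels <- as.integer(factor(labels, levels = unique(labels)))
  structure(
    list(partition = tibble::tibble(node = nodes, community = as.character(labels)),
         algorithm = algorithm, measure = measure, seed = seed,
         details = details),
    class = "cns_communities"
  )
}

#' @export
print.cns_communities <- function(x, ...) {
  k <- length(unique(x$partition$community))
  cat("<cns_communities> ", x$algorithm,
      if (!is.null(x$measure)) paste0(" + ", x$measure), ": ",
      nrow(x$partition), " nodes in ", k, " communities",
      if (!is.null(x$details$wq)) paste0(", WQ = ", signif(x$details$wq, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Detect communities in an attributed network
#'
#' End-to-end driver: computes the chosen node similarity, weights the graph's
#' edges with it, and runs the chosen weighted clustering algorithm. This is
#' the package's main entry point.
#'
#' @param g An [attributed_graph()].
#' @param measure Similarity measure (see [similarity_matrix()]).
#' @param algorithm `"bgll"`, `"slpa"` or `"kmedoids"`.
#' @param alpha_scheme Passed to the similarity computation.
#' @param iterations SLPA iterations.
#' @param K Number of clusters for K-medoids.
#' @param seed Optional integer seed.
#' @return A `cns_communities` object: `$partition` is a tibble
#'   (`node`, `community`), `$details$wq` the weighted modularity of the
#'   result (when total weight is positive). Use [generics::tidy()] for the
#'   partition and [generics::glance()] for a one-row summary.
#' @examples
#' g <- toy_fixture()$graph
#' fit <- detect_communities(g, measure = "cns1", algorithm = "bgll", seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
detect_communities <- function(g, measure = "cns1",
                               algorithm = c("bgll", "slpa", "kmedoids"),
                               alpha_scheme = c("others-uniform", "all-uniform"),
                               iterations = 20L, K = NULL, seed = NULL) {
  algorithm <- match.arg(algorithm)
  alpha_scheme <- match.arg(alpha_scheme)
  w <- build_weighted_graph(g, measure, alpha_scheme)
  fit <- switch(algorithm,
    bgll = bgll(w, seed = seed),
    slpa = slpa(w, iterations = iterations, seed = seed),
    kmedoids = {
      if (is.null(K)) stop("K must be given for kmedoids", call. = FALSE)
      kmedoids(w, K = K, seed = seed)
    })
  fit$measure <- measure
  if (total_weight(w) > 0 && is.null(fit$details$wq)) {
    fit$details$wq <- weighted_modularity(w, fit$partition)
  }
  fit
}

#' Repeat a stochastic detection run and summarise its scores
#'
#' Runs the configured algorithm `restarts` times with per-restart seeds
#' derived deterministically from the master seed, scores every run against
#' the ground truth, and summarises. Intended for SLPA and K-medoids, whose
#' results vary across runs.
#'
#' @inheritParams detect_communities
#' @param truth Ground-truth partition (see [as_partition()]).
#' @param restarts Number of repetitions.
#' @param seed Master seed from which all per-restart seeds are derived.
#' @return An object of class `cns_repeated`: `$runs` is a tibble with one row
#'   per restart (`restart`, `nmi`, `f_measure`, `accuracy`, `wq`, `k`) and
#'   `$summary` a one-row tibble of means and standard deviations.
#' @export
run_repeated <- function(g, truth, measure = "cns1",
                         algorithm = c("bgll", "slpa", "kmedoids"),
                         restarts = 100L,
                         alpha_scheme = c("others-uniform", "all-uniform"),
                         iterations = 20L, K = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  alpha_scheme <- match.arg(alpha_scheme)
  restarts <- as.integer(restarts)
  stopifnot(restarts >= 1L)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, restarts))
  w <- build_weighted_graph(g, measure, alpha_scheme)
  runs <- purrr::map_dfr(seq_len(restarts), function(r) {
    fit <- switch(algorithm,
      bgll = bgll(w, seed = seeds[r]),
      slpa = slpa(w, iterations = iterations, seed = seeds[r]),
      kmedoids = kmedoids(w, K = K, seed = seeds[r]))
    sc <- evaluate_partition(truth, fit$partition)
    wq <- if (total_weight(w) > 0) weighted_modularity(w, fit$partition) else NA_real_
    dplyr::mutate(sc, restart = r, wq = wq,
                  k = length(unique(fit$partition$community)))
  })
  summary <- dplyr::summarise(
    runs,
    mean_nmi = mean(.data$nmi), sd_nmi = stats::sd(.data$nmi),
    mean_f_measure = mean(.data$f_measure), sd_f_measure = stats::sd(.data$f_measure),
    mean_accuracy = mean(.data$accuracy), sd_accuracy = stats::sd(.data$accuracy),
    mean_wq = mean(.data$wq), n_runs = dplyr::n()
  )
  structure(list(runs = runs, summary = summary, algorithm = algorithm,
                 measure = measure, seed = seed),
            class = "cns_repeated")
}

#' @export
print.cns_repeated <- function(x, ...) {
  cat("<cns_repeated> ", x$algorithm, " + ", x$measure, ", ",
      x$summary$n_runs, " runs\n", sep = "")
  print(x$summary)
  invisible(x)
}
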