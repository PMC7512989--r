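# Independent oracles: brute-force counterparts of the package's closed-form
# computations, used only to generate expected values in tests.

# subset-minimisation form of the inter-relative similarity:
# min over all B subseteq Fn of 2 - ICP(B | x) - ICP(complement(B) | y)
oracle_inter_relative <- function(g, m, n, x, y) {
  vals_n <- g$domains[[n]]
  fx <- g$attributes[[m]] == x
  fy <- g$attributes[[m]] == y
  fn <- g$attributes[[n]]
  best <- Inf
  for (mask in 0:(2^length(vals_n) - 1)) {
    B <- vals_n[bitwAnd(mask, 2^(seq_along(vals_n) - 1)) > 0]
    Bbar <- setdiff(vals_n, B)
    px <- sum(fx & fn %in% B) / sum(fx)
    py <- sum(fy & fn %in% Bbar) / sum(fy)
    best <- min(best, 2 - px - py)
  }
  best
}

# NMI directly from the contingency-table definition, arithmetic-mean
# entropy normalisation, computed without reusing package internals
oracle_nmi <- function(truth, detected) {
  tt <- factor(truth)
  dd <- factor(detected)
  ct <- table(tt, dd)
  n <- sum(ct)
  num <- 0
  for (r in seq_len(nrow(ct))) for (k in seq_len(ncol(ct))) {
    if (ct[r, k] > 0) {
      num <- num - 2 * (ct[r, k] / n) *
        log(n * ct[r, k] / (sum(ct[r, ]) * sum(ct[, k])))
    }
  }
  den <- sum(sapply(rowSums(ct), function(a) a / n * log(a / n))) +
    sum(sapply(colSums(ct), function(b) b / n * log(b / n)))
  if (den == 0) return(if (identical(as.integer(tt), as.integer(dd)) ||
                           (nlevels(tt) == 1 && nlevels(dd) == 1)) 1 else 0)
  num / den
}

# clustering accuracy by exhaustive enumeration of one-to-one community
# matchings (all injections of the smaller side into the larger)
oracle_accuracy <- function(truth, detected) {
  ct <- unclass(table(truth, detected))
  if (nrow(ct) > ncol(ct)) ct <- t(ct)
  R <- nrow(ct); K <- ncol(ct)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- 0
  for (p in perms(seq_len(K))) {
    tc <- sum(ct[cbind(seq_len(R), p[seq_len(R)])])
    best <- max(best, tc)
  }
  best / sum(ct)
}

# small random attributed graph for property tests
random_attributed_graph <- function(n_nodes = 8, n_attr = 2, max_domain = 4,
                                    p_edge = 0.3) {
  nodes <- paste0("v", seq_len(n_nodes))
  attrs <- tibble::tibble(node = nodes)
  for (a in seq_len(n_attr)) {
    k <- sample(2:max_domain, 1)
    attrs[[paste0("a", a)]] <- paste0("x", sample.int(k, n_nodes, replace = TRUE))
  }
  pairs <- t(utils::combn(n_nodes, 2))
  hit <- stats::runif(nrow(pairs)) < p_edge
  edges <- if (any(hit)) {
    data.frame(from = nodes[pairs[hit, 1]], to = nodes[pairs[hit, 2]])
  } else NULL
  attributed_graph(edges, attrs)
}

# two 4-cliques joined by a single bridge edge, unit weights
bridged_cliques <- function() {
  cl <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  weighted_graph(paste0("v", 1:8), cl, rep(1, nrow(cl)))
}

clique_truth <- function() {
  tibble::tibble(node = paste0("v", 1:8), community = rep(c("A", "B"), each = 4))
}
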