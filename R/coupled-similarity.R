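#' @importFrom rlang .data
NULL

# alpha weights over the other attributes for a given focal attribute.
# others-uniform: 1/(M-1) on each other attribute (reproduces the worked
# two-attribute example, where the single other attribute carries full weight);
# all-uniform: 1/M on each attribute including the focal one, so the weights on
# the others sum to (M-1)/M.
alpha_weights <- function(M, m, alpha_scheme = c("others-uniform", "all-uniform")) {
  alpha_scheme <- match.arg(alpha_scheme)
  others <- setdiff(seq_len(M), m)
  w <- if (alpha_scheme == "others-uniform") rep(1 / (M - 1), length(others))
       else rep(1 / M, length(others))
  stats::setNames(w, others)
}

#' Intra-attribute coupled similarity of two attribute values
#'
#' Frequency-based similarity between two values `x`, `y` of one categorical
#' attribute: `|g(x)||g(y)| / (|g(x)| + |g(y)| + |g(x)||g(y)|)`, where `g(x)`
#' is the set of nodes carrying value `x`. Rarer value pairs score lower; the
#' similarity lies in `[1/3, 1)` and is defined (by the same formula) for
#' `x = y`.
#'
#' @param g An [attributed_graph()].
#' @param attribute Attribute name or index.
#' @param x,y Values in the attribute's domain.
#' @return A number in `[1/3, 1)`.
#' @examples
#' g <- toy_fixture()$graph
#' intra_attribute_similarity(g, "country", "AU", "CN")  # 6/11
#' @export
intra_attribute_similarity <- function(g, attribute, x, y) {
  m <- attr_index(g, attribute)
  check_value(g, m, x); check_value(g, m, y)
  nx <- sum(g$attributes[[m]] == x)
  ny <- sum(g$attributes[[m]] == y)
  (nx * ny) / (nx + ny + nx * ny)
}

#' Information conditional probability (ICP)
#'
#' The fraction of the nodes carrying value `value` on attribute
#' `given_attribute` whose value on `subset_attribute` falls in the value
#' subset `subset`. `icp(g, n, B, m, x)` is monotone nondecreasing in `B`,
#' equals 0 for the empty subset and 1 for the full domain.
#'
#' @inheritParams intra_attribute_similarity
#' @param subset_attribute Attribute whose values form the subset.
#' @param subset Character vector of values of `subset_attribute` (may be
#'   empty).
#' @param given_attribute The conditioning attribute (must differ from
#'   `subset_attribute`).
#' @param value A value of `given_attribute`.
#' @return A probability in `[0, 1]`.
#' @examples
#' g <- toy_fixture()$graph
#' icp(g, "topic", "DM", "country", "AU")  # 1
#' @export
icp <- function(g, subset_attribute, subset, given_attribute, value) {
  n <- attr_index(g, subset_attribute)
  m <- attr_index(g, given_attribute)
  if (n == m) stop("subset and conditioning attribute must differ", call. = FALSE)
  for (b in subset) check_value(g, n, b)
  check_value(g, m, value)
  cond <- g$attributes[[m]] == value
  sum(cond & g$attributes[[n]] %in% subset) / sum(cond)
}

#' Inter-relative coupled similarity of two values via one other attribute
#'
#' The similarity of values `x`, `y` of the focal attribute induced by their
#' co-occurrence with the values of one `other` attribute: the minimum over
#' all value subsets `B` of the other attribute of
#' `2 - ICP(B | x) - ICP(complement(B) | y)`. The subset minimisation has the
#' closed form `sum_w min(ICP({w} | x), ICP({w} | y))` over single values `w`
#' (take `B = {w : ICP(w|x) >= ICP(w|y)}`), which is what is computed here;
#' it lies in `[0, 1]` and equals 1 when `x = y`.
#'
#' @inheritParams intra_attribute_similarity
#' @param other The other attribute (name or index), distinct from
#'   `attribute`.
#' @return A number in `[0, 1]`.
#' @examples
#' g <- toy_fixture()$graph
#' inter_relative_similarity(g, "country", "topic", "AU", "CN")  # 2/3
#' @export
inter_relative_similarity <- function(g, attribute, other, x, y) {
  m <- attr_index(g, attribute)
  n <- attr_index(g, other)
  if (n == m) stop("'other' must differ from the focal attribute", call. = FALSE)
  check_value(g, m, x); check_value(g, m, y)
  fx <- g$attributes[[m]] == x
  fy <- g$attributes[[m]] == y
  fn <- g$attributes[[n]]
  px <- vapply(g$domains[[n]], function(w) sum(fx & fn == w) / sum(fx), numeric(1))
  py <- vapply(g$domains[[n]], function(w) sum(fy & fn == w) / sum(fy), numeric(1))
  sum(pmin(px, py))
}

#' Inter-attribute coupled similarity of two attribute values
#'
#' Weighted sum over all other attributes of the inter-relative similarity
#' ([inter_relative_similarity()]). The default `alpha_scheme`
#' `"others-uniform"` spreads weight `1/(M-1)` over the `M - 1` other
#' attributes so the result lies in `[0, 1]` and equals 1 at `x = y`;
#' `"all-uniform"` uses weight `1/M` per attribute. For a single-attribute
#' graph the empty sum is defined as 1 (the sole attribute is treated as
#' self-consistent) and a message is emitted.
#'
#' @inheritParams intra_attribute_similarity
#' @param alpha_scheme `"others-uniform"` (default) or `"all-uniform"`.
#' @return A nonnegative number (in `[0, 1]` under the default scheme).
#' @export
inter_attribute_similarity <- function(g, attribute, x, y,
                                       alpha_scheme = c("others-uniform", "all-uniform")) {
  alpha_scheme <- match.arg(alpha_scheme)
  m <- attr_index(g, attribute)
  M <- n_attributes(g)
  check_value(g, m, x); check_value(g, m, y)
  if (M == 1L) {
    message("single-attribute graph: inter-attribute similarity defined as 1")
    return(1)
  }
  w <- alpha_weights(M, m, alpha_scheme)
  sum(vapply(names(w), function(n) {
    w[[n]] * inter_relative_similarity(g, m, as.integer(n), x, y)
  }, numeric(1)))
}

#' Coupled attribute value similarity
#'
#' Product of the intra-attribute ([intra_attribute_similarity()]) and
#' inter-attribute ([inter_attribute_similarity()]) coupled similarities for a
#' value pair of one attribute.
#'
#' @inheritParams inter_attribute_similarity
#' @return A number in `[0, 1)`.
#' @export
coupled_value_similarity <- function(g, attribute, x, y,
                                     alpha_scheme = c("others-uniform", "all-uniform")) {
  intra_attribute_similarity(g, attribute, x, y) *
    inter_attribute_similarity(g, attribute, x, y, alpha_scheme)
}

#' Attribute-to-structure similarity of two attribute values
#'
#' The homophily term: the number of adjacency relations between the node
#' group carrying value `x` and the group carrying `y`, divided by the number
#' of possible relations `|g(x)||g(y)|`. The sum runs over ordered node pairs
#' exactly as defined, so for `x = y` each edge inside the group counts twice
#' against a denominator of `|g(x)|^2`.
#'
#' @inheritParams intra_attribute_similarity
#' @return A number in `[0, 1]`.
#' @examples
#' g <- toy_fixture()$graph
#' attribute_structure_similarity(g, "country", "AU", "CN")  # 0.5
#' @export
attribute_structure_similarity <- function(g, attribute, x, y) {
  m <- attr_index(g, attribute)
  check_value(g, m, x); check_value(g, m, y)
  vals <- g$attributes[[m]]
  e <- g$edges
  if (!nrow(e)) return(0)
  vu <- vals[e[, 1L]]
  vv <- vals[e[, 2L]]
  cross <- sum((vu == x & vv == y) | (vu == y & vv == x))
  if (x == y) cross <- 2L * sum(vu == x & vv == x)
  cross / (sum(vals == x) * sum(vals == y))
}

#' Coupled attribute similarity (CAS) between two nodes
#'
#' Attribute-only node similarity: the sum over attributes of the coupled
#' attribute value similarity evaluated at the two nodes' value pair.
#'
#' @inheritParams inter_attribute_similarity
#' @param i,j Node identifiers.
#' @return A number in `[0, M]`.
#' @export
cas <- function(g, i, j, alpha_scheme = c("others-uniform", "all-uniform")) {
  alpha_scheme <- match.arg(alpha_scheme)
  ii <- node_index(g, i); jj <- node_index(g, j)
  sum(vapply(seq_len(n_attributes(g)), function(m) {
    coupled_value_similarity(g, m, g$attributes[[m]][ii], g$attributes[[m]][jj],
                             alpha_scheme)
  }, numeric(1)))
}

#' Coupled node similarity (CNS) between two nodes
#'
#' The full similarity fusing attribute value frequency (intra), attribute
#' co-occurrence (inter) and attribute-to-edge consistency (structure). Four
#' combinations of the three per-attribute terms are supported, each summed
#' over attributes:
#' \describe{
#'   \item{`cns1`}{`intra * inter * struct` (the default definition)}
#'   \item{`cns2`}{`(intra + inter) * struct`}
#'   \item{`cns3`}{`intra * inter + struct`}
#'   \item{`cns4`}{`intra + inter + struct`}
#' }
#'
#' @inheritParams cas
#' @param variant One of `"cns1"`, `"cns2"`, `"cns3"`, `"cns4"`.
#' @return A nonnegative number; `cns1` lies in `[0, M]`.
#' @examples
#' g <- toy_fixture()$graph
#' round(cns(g, "George", "Ying"), 2)   # 0.41
#' round(cns(g, "George", "Jones"), 2)  # 0.29
#' @export
cns <- function(g, i, j, variant = c("cns1", "cns2", "cns3", "cns4"),
                alpha_scheme = c("others-uniform", "all-uniform")) {
  variant <- match.arg(variant)
  alpha_scheme <- match.arg(alpha_scheme)
  ii <- node_index(g, i); jj <- node_index(g, j)
  sum(vapply(seq_len(n_attributes(g)), function(m) {
    x <- g$attributes[[m]][ii]; y <- g$attributes[[m]][jj]
    ia <- intra_attribute_similarity(g, m, x, y)
    ie <- inter_attribute_similarity(g, m, x, y, alpha_scheme)
    as_ <- attribute_structure_similarity(g, m, x, y)
    combine_cns(ia, ie, as_, variant)
  }, numeric(1)))
}

combine_cns <- function(ia, ie, as_, variant) {
  switch(variant,
         cns1 = ia * ie * as_,
         cns2 = (ia + ie) * as_,
         cns3 = ia * ie + as_,
         cns4 = ia + ie + as_)
}

#' Baseline node similarities
#'
#' The comparison measures: raw `adjacency`; `cosine` and `jaccard` overlap of
#' the two nodes' neighbour sets (structure-only); and the simple matching
#' coefficient `smc`, the fraction of attributes on which the two nodes agree
#' (attribute-only). Cosine/Jaccard of a pair involving an isolated node is 0
#' by convention.
#'
#' @inheritParams cas
#' @param kind One of `"adjacency"`, `"cosine"`, `"jaccard"`, `"smc"`.
#' @return A number in `[0, 1]`.
#' @export
baseline_similarity <- function(g, i, j,
                                kind = c("adjacency", "cosine", "jaccard", "smc")) {
  kind <- match.arg(kind)
  ii <- node_index(g, i); jj <- node_index(g, j)
  if (kind == "smc") {
    vi <- vapply(g$attributes, `[`, "", ii)
    vj <- vapply(g$attributes, `[`, "", jj)
    return(mean(vi == vj))
  }
  adj <- adjacency_list(g)
  if (kind == "adjacency") return(as.numeric(jj %in% adj[[ii]]))
  ni <- adj[[ii]]; nj <- adj[[jj]]
  if (!length(ni) || !length(nj)) return(0)
  inter <- length(intersect(ni, nj))
  if (kind == "cosine") inter / sqrt(length(ni) * length(nj))
  else inter / length(union(ni, nj))
}

# ---- value-pair tables and matrices (the two-phase driver) ------------------

# Per-attribute value-pair machinery, vectorised over the whole domain:
# square matrices over the attribute's values for intra, inter, their product,
# and the structure term. Phase one of the similarity driver; node-pair
# evaluation (phase two) is pure table lookup.
vp_tables_one <- function(g, m, alpha_scheme) {
  vals <- g$domains[[m]]
  R <- length(vals)
  fm <- factor(g$attributes[[m]], levels = vals)
  counts <- as.integer(table(fm))
  M <- n_attributes(g)

  D_ia <- outer(counts, counts, function(a, b) (a * b) / (a + b + a * b))

  if (M == 1L) {
    D_ie <- matrix(1, R, R)
  } else {
    D_ie <- matrix(0, R, R)
    w <- alpha_weights(M, m, alpha_scheme)
    for (n_chr in names(w)) {
      n <- as.integer(n_chr)
      fn <- factor(g$attributes[[n]], levels = g$domains[[n]])
      ct <- table(fm, fn)                       # R x Rn co-occurrence counts
      P <- ct / counts                          # row-conditional ICP of singletons
      D_mn <- matrix(0, R, R)
      for (k in seq_len(ncol(P))) {
        D_mn <- D_mn + outer(P[, k], P[, k], pmin)
      }
      D_ie <- D_ie + w[[n_chr]] * D_mn
    }
  }

  # ordered-pair edge counts between value groups
  Ecnt <- matrix(0, R, R)
  if (nrow(g$edges)) {
    vu <- as.integer(fm[g$edges[, 1L]])
    vv <- as.integer(fm[g$edges[, 2L]])
    for (e in seq_along(vu)) {
      Ecnt[vu[e], vv[e]] <- Ecnt[vu[e], vv[e]] + 1
      Ecnt[vv[e], vu[e]] <- Ecnt[vv[e], vu[e]] + 1
    }
  }
  D_as <- Ecnt / outer(counts, counts)

  dimnames(D_ia) <- dimnames(D_ie) <- dimnames(D_as) <- list(vals, vals)
  list(values = vals, counts = counts, intra = D_ia, inter = D_ie,
       attr = D_ia * D_ie, struct = D_as, value_index = as.integer(fm))
}

#' Per-attribute value-pair similarity table
#'
#' Materialises, for one attribute, all four per-value-pair quantities — the
#' intra-attribute, inter-attribute, coupled attribute (their product) and
#' attribute-to-structure similarities — for every unordered value pair
#' including matched pairs. This is the precomputation phase of the similarity
#' driver; node-pair similarities are lookups into these tables.
#'
#' @inheritParams inter_attribute_similarity
#' @return A tibble with columns `attribute`, `x`, `y`, `delta_intra`,
#'   `delta_inter`, `delta_attr`, `delta_struct`.
#' @export
value_pair_table <- function(g, attribute,
                             alpha_scheme = c("others-uniform", "all-uniform")) {
  alpha_scheme <- match.arg(alpha_scheme)
  m <- attr_index(g, attribute)
  tb <- vp_tables_one(g, m, alpha_scheme)
  R <- length(tb$values)
  idx <- which(upper.tri(matrix(0, R, R), diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    attribute = names(g$attributes)[m],
    x = tb$values[idx[, 1L]],
    y = tb$values[idx[, 2L]],
    delta_intra = tb$intra[idx],
    delta_inter = tb$inter[idx],
    delta_attr = tb$attr[idx],
    delta_struct = tb$struct[idx]
  )
}

cns_measures <- c("cns1", "cns2", "cns3", "cns4")
all_measures <- c("adjacency", "cosine", "jaccard", "smc", "cas", cns_measures)

#' Node-pair similarity matrix
#'
#' Builds the symmetric `|V| x |V|` similarity matrix for any supported
#' measure. The driver precomputes the per-attribute value-pair tables once
#' and then fills node pairs by lookup. For the CNS family the default
#' materialises only adjacent pairs (all that edge weighting needs — weights
#' are zero off the adjacency anyway); `full = TRUE` fills every pair, which
#' the attribute-only and structure-overlap baselines use by default.
#'
#' @inheritParams inter_attribute_similarity
#' @param measure One of `"adjacency"`, `"cosine"`, `"jaccard"`, `"smc"`,
#'   `"cas"`, `"cns1"`, `"cns2"`, `"cns3"`, `"cns4"`.
#' @param full Logical; materialise all node pairs (default `TRUE` except for
#'   the CNS family).
#' @return A numeric matrix with node identifiers as dimnames and attributes
#'   `measure` and `alpha_scheme`.
#' @export
similarity_matrix <- function(g, measure = "cns1",
                              alpha_scheme = c("others-uniform", "all-uniform"),
                              full = NULL) {
  measure <- match.arg(measure, all_measures)
  alpha_scheme <- match.arg(alpha_scheme)
  if (is.null(full)) full <- !(measure %in% cns_measures)
  n <- n_nodes(g)
  S <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))

  if (measure == "adjacency") {
    if (nrow(g$edges)) {
      S[g$edges] <- 1
      S[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
    }
  } else if (measure %in% c("cosine", "jaccard")) {
    adj <- adjacency_list(g)
    deg <- lengths(adj)
    A <- matrix(0, n, n)
    if (nrow(g$edges)) {
      A[g$edges] <- 1
      A[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
    }
    common <- A %*% A                      # shared-neighbour counts
    if (measure == "cosine") {
      den <- sqrt(outer(deg, deg))
    } else {
      den <- outer(deg, deg, `+`) - common # |union| = di + dj - |intersection|
    }
    ok <- den > 0
    S[ok] <- common[ok] / den[ok]
    diag(S) <- ifelse(deg > 0, 1, 0)
  } else if (measure == "smc") {
    M <- n_attributes(g)
    for (m in seq_len(M)) {
      v <- g$attributes[[m]]
      S <- S + outer(v, v, `==`) / M
    }
  } else {
    M <- n_attributes(g)
    tabs <- lapply(seq_len(M), function(m) vp_tables_one(g, m, alpha_scheme))
    per_attr <- function(tb) {
      if (measure == "cas") tb$attr
      else combine_cns(tb$intra, tb$inter, tb$struct, measure)
    }
    if (full) {
      for (m in seq_len(M)) {
        vi <- tabs[[m]]$value_index
        S <- S + per_attr(tabs[[m]])[vi, vi]
      }
    } else if (nrow(g$edges)) {
      e <- g$edges
      s <- numeric(nrow(e))
      for (m in seq_len(M)) {
        vi <- tabs[[m]]$value_index
        Tm <- per_attr(tabs[[m]])
        s <- s + Tm[cbind(vi[e[, 1L]], vi[e[, 2L]])]
      }
      S[e] <- s
      S[e[, c(2L, 1L), drop = FALSE]] <- s
    }
  }
  attr(S, "measure") <- measure
  attr(S, "alpha_scheme") <- alpha_scheme
  S
}

#' Node-pair similarities as a tidy table
#'
#' @inheritParams similarity_matrix
#' @param pairs `"adjacent"` (default) to list the graph's edges, `"all"` for
#'   every unordered node pair.
#' @return A tibble `from`, `to`, `similarity`.
#' @export
node_similarity <- function(g, measure = "cns1",
                            alpha_scheme = c("others-uniform", "all-uniform"),
                            pairs = c("adjacent", "all")) {
  pairs <- match.arg(pairs)
  S <- similarity_matrix(g, measure, alpha_scheme, full = (pairs == "all"))
  if (pairs == "adjacent") {
    e <- g$edges
    tibble::tibble(from = g$nodes[e[, 1L]], to = g$nodes[e[, 2L]],
                   similarity = S[e])
  } else {
    idx <- which(upper.tri(S), arr.ind = TRUE)
    tibble::tibble(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]],
                   similarity = S[idx])
  }
}
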