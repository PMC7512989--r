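#' Contingency table of two partitions
#'
#' Cross-tabulates ground-truth against detected community memberships over a
#' common node set. Rows are truth communities, columns detected ones; row
#' sums are the truth community sizes, column sums the detected sizes.
#'
#' @param truth,detected Partitions of the same node set (see
#'   [as_partition()]).
#' @return An integer matrix.
#' @export
contingency_table <- function(truth, detected) {
  t <- as_partition(truth)
  d <- as_partition(detected)
  if (!setequal(t$node, d$node)) {
    stop("partitions are over different node sets", call. = FALSE)
  }
  dd <- d$community[match(t$node, d$node)]
  as.matrix(table(truth = t$community, detected = dd))
}

#' Normalized mutual information of two partitions
#'
#' Mutual information of the two community assignments normalised by the
#' arithmetic mean of the two partition entropies
#' (`NMI = -2 I / (H_truth_term + H_detected_term)` on the contingency table,
#' with the convention `0 log 0 = 0`). Symmetric in its arguments, invariant
#' to relabelling, in `[0, 1]`, and 1 for identical partitions. When both
#' partitions are trivial (a single community, so both entropies vanish) the
#' value is defined as 1 if they are identical and 0 otherwise.
#'
#' @inheritParams contingency_table
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(truth, detected) {
  ct <- contingency_table(truth, detected)
  n <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  ha <- sum(a / n * log(a / n))
  hb <- sum(b / n * log(b / n))
  if (ha == 0 && hb == 0) {                  # both trivial partitions
    return(if (nrow(ct) == 1L && ncol(ct) == 1L) 1 else 0)
  }
  nz <- ct > 0
  num <- -2 * sum(ct[nz] / n * log(n * ct[nz] / outer(a, b)[nz]))
  val <- num / (ha + hb)
  min(max(val, 0), 1)
}

#' F-measure of a detected partition against ground truth
#'
#' For every truth community `U` the best harmonic mean of precision
#' (`|U n C| / |C|`) and recall (`|U n C| / |U|`) over the detected
#' communities `C` is taken, and the per-community bests are averaged weighted
#' by truth community size.
#'
#' @inheritParams contingency_table
#' @return A number in `(0, 1]`.
#' @export
f_measure <- function(truth, detected) {
  ct <- contingency_table(truth, detected)
  n <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  best <- vapply(seq_len(nrow(ct)), function(r) {
    p <- ct[r, ] / b
    rc <- ct[r, ] / a[r]
    f <- ifelse(p + rc > 0, 2 * p * rc / (p + rc), 0)
    max(f)
  }, numeric(1))
  sum(a / n * best)
}

# exact maximum-weight one-to-one matching on a contingency table:
# bitmask DP over the smaller dimension (columns after orientation)
assignment_max <- function(ct) {
  if (nrow(ct) < ncol(ct)) ct <- t(ct)
  R <- nrow(ct); K <- ncol(ct)
  if (K > 20L) stop("too many communities for exact matching (> 2^20 states)",
                    call. = FALSE)
  nstate <- bitwShiftL(1L, K)
  dp <- rep(-Inf, nstate)
  dp[1L] <- 0
  for (r in seq_len(R)) {
    new_dp <- dp                             # row r unmatched
    for (mask in which(is.finite(dp)) - 1L) {
      for (k in seq_len(K)) {
        bit <- bitwShiftL(1L, k - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          m2 <- bitwOr(mask, bit) + 1L
          cand <- dp[mask + 1L] + ct[r, k]
          if (cand > new_dp[m2]) new_dp[m2] <- cand
        }
      }
    }
    dp <- new_dp
  }
  max(dp)
}

#' Clustering accuracy under optimal community matching
#'
#' The fraction of nodes whose detected label maps to their true community
#' under the best one-to-one matching between detected and truth communities
#' (maximum-weight assignment on the contingency table, computed exactly;
#' surplus unmatched communities contribute nothing).
#'
#' @inheritParams contingency_table
#' @return A number in `(0, 1]`.
#' @export
clustering_accuracy <- function(truth, detected) {
  ct <- contingency_table(truth, detected)
  assignment_max(ct) / sum(ct)
}

#' Score a detected partition against ground truth
#'
#' One-stop evaluation: [nmi()], [f_measure()] and [clustering_accuracy()].
#'
#' @inheritParams contingency_table
#' @return A one-row tibble with columns `nmi`, `f_measure`, `accuracy`.
#' @examples
#' toy <- toy_fixture()
#' fit <- detect_communities(toy$graph, "cns1", "bgll", seed = 1)
#' evaluate_partition(toy$truth, fit$partition)
#' @export
evaluate_partition <- function(truth, detected) {
  if (inherits(detected, "cns_communities")) detected <- detected$partition
  tibble::tibble(
    nmi = nmi(truth, detected),
    f_measure = f_measure(truth, detected),
    accuracy = clustering_accuracy(truth, detected)
  )
}
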