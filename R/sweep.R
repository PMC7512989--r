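#' Sweep benchmark difficulty against similarity measures and algorithms
#'
#' Runs the full experiment grid: for every combination of mixing parameter
#' `mu`, similarity `measure` and detection `algorithm`, generates
#' `n_seeds` benchmark networks, detects communities (stochastic algorithms
#' are additionally repeated `restarts` times per network), scores against the
#' planted partition, and records one summary row per cell. Failures in a
#' cell are caught, reported as a warning and leave `NA` scores so the sweep
#' continues. The whole sweep is deterministic under the master `seed`.
#'
#' @param mu Numeric vector of mixing parameters.
#' @param measures Character vector of similarity measures (see
#'   [similarity_matrix()]).
#' @param algorithms Character vector among `"bgll"`, `"slpa"`, `"kmedoids"`.
#' @param spec Baseline [benchmark_spec()]; its `mu` is overridden per cell.
#' @param n_seeds Number of benchmark networks per cell.
#' @param restarts Repetitions per network for the stochastic algorithms
#'   (ignored for BGLL, which is run once per network seed).
#' @param alpha_scheme Passed to the similarity computation.
#' @param iterations SLPA iterations.
#' @param seed Master seed.
#' @return A tibble of class `cns_sweep`, one row per
#'   `(mu, measure, algorithm)` cell with columns `mean_nmi`, `mean_f_measure`,
#'   `mean_accuracy`, `mean_wq`, their standard deviations across networks,
#'   and `n_runs`.
#' @examples
#' \donttest{
#' sw <- sweep_benchmark(mu = c(0.1, 0.5), measures = c("adjacency", "cns1"),
#'                       n_seeds = 2, seed = 1)
#' autoplot(sw)
#' }
#' @export
sweep_benchmark <- function(mu = seq(0.1, 0.9, by = 0.1),
                            measures = "cns1",
                            algorithms = "bgll",
                            spec = benchmark_spec(),
                            n_seeds = 10L,
                            restarts = 10L,
                            alpha_scheme = c("others-uniform", "all-uniform"),
                            iterations = 20L,
                            seed = 1L) {
  alpha_scheme <- match.arg(alpha_scheme)
  grid <- tidyr::expand_grid(mu = mu, measure = measures, algorithm = algorithms)
  cell_seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, nrow(grid) * n_seeds),
           nrow = nrow(grid)))

  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(cell) {
    cfg <- grid[cell, ]
    cell_spec <- spec
    cell_spec$mu <- cfg$mu
    res <- tryCatch({
      per_net <- purrr::map_dfr(seq_len(n_seeds), function(s) {
        net_seed <- cell_seeds[cell, s]
        bm <- generate_benchmark(cell_spec, seed = net_seed)
        K <- length(unique(bm$truth$community))
        if (cfg$algorithm == "bgll") {
          fit <- detect_communities(bm$graph, cfg$measure, "bgll",
                                    alpha_scheme, seed = net_seed)
          sc <- evaluate_partition(bm$truth, fit)
          dplyr::mutate(sc, wq = fit$details$wq %||% NA_real_)
        } else {
          rep <- run_repeated(bm$graph, bm$truth, cfg$measure, cfg$algorithm,
                              restarts = restarts, alpha_scheme = alpha_scheme,
                              iterations = iterations, K = K, seed = net_seed)
          tibble::tibble(nmi = rep$summary$mean_nmi,
                         f_measure = rep$summary$mean_f_measure,
                         accuracy = rep$summary$mean_accuracy,
                         wq = rep$summary$mean_wq)
        }
      })
      dplyr::summarise(
        per_net,
        mean_nmi = mean(.data$nmi), sd_nmi = stats::sd(.data$nmi),
        mean_f_measure = mean(.data$f_measure), sd_f_measure = stats::sd(.data$f_measure),
        mean_accuracy = mean(.data$accuracy), sd_accuracy = stats::sd(.data$accuracy),
        mean_wq = mean(.data$wq), n_runs = dplyr::n()
      )
    }, error = function(e) {
      warning("sweep cell (mu = ", cfg$mu, ", ", cfg$measure, ", ",
              cfg$algorithm, ") failed: ", conditionMessage(e), call. = FALSE)
      tibble::tibble(mean_nmi = NA_real_, sd_nmi = NA_real_,
                     mean_f_measure = NA_real_, sd_f_measure = NA_real_,
                     mean_accuracy = NA_real_, sd_accuracy = NA_real_,
                     mean_wq = NA_real_, n_runs = 0L)
    })
    dplyr::bind_cols(cfg, res)
  })
  class(rows) <- c("cns_sweep", class(rows))
  attr(rows, "seed") <- seed
  rows
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarise community detection results
#'
#' `tidy()` on a `cns_communities` object returns the node-to-community
#' assignment; `glance()` a one-row summary (algorithm, measure, number of
#' communities, weighted modularity). On a `cns_repeated` object `tidy()`
#' returns the per-restart scores and `glance()` their means.
#'
#' @param x A `cns_communities` or `cns_repeated` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cns_communities <- function(x, ...) x$partition

#' @rdname tidy.cns_communities
#' @export
glance.cns_communities <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    measure = x$measure %||% NA_character_,
    n_communities = length(unique(x$partition$community)),
    wq = x$details$wq %||% NA_real_,
    converged = x$details$converged %||% NA
  )
}

#' @rdname tidy.cns_communities
#' @export
tidy.cns_repeated <- function(x, ...) x$runs

#' @rdname tidy.cns_communities
#' @export
glance.cns_repeated <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(algorithm = x$algorithm, measure = x$measure),
                   x$summary)
}

#' Plot a benchmark sweep
#'
#' Mean accuracy (or another score) against the mixing parameter, one line per
#' similarity measure, faceted by algorithm when several are present.
#'
#' @param object A `cns_sweep` tibble from [sweep_benchmark()].
#' @param metric Column to plot, e.g. `"mean_accuracy"` (default),
#'   `"mean_nmi"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cns_sweep <- function(object, metric = "mean_accuracy", ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$mu, y = .data[[metric]],
                                    colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mixing parameter mu", y = metric, colour = "measure") +
    ggplot2::theme_minimal()
  if (length(unique(object$algorithm)) > 1L) {
    p <- p + ggplot2::facet_wrap(~algorithm)
  }
  p
}

#' Plot a network coloured by community
#'
#' Force-directed layout of the graph with nodes coloured by their community
#' assignment; a quick visual check of a detection result.
#'
#' @param g An [attributed_graph()].
#' @param partition A partition of `g`'s nodes or a `cns_communities` object.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_communities <- function(g, partition, seed = 1L) {
  if (inherits(partition, "cns_communities")) partition <- partition$partition
  p <- as_partition(partition)
  ig <- as_igraph(g)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(ig))
  nodes <- tibble::tibble(
    node = igraph::V(ig)$name, x = xy[, 1L], y = xy[, 2L],
    community = p$community[match(igraph::V(ig)$name, p$node)]
  )
  et <- edge_table(g)
  segs <- dplyr::mutate(
    et,
    x = nodes$x[match(.data$from, nodes$node)],
    y = nodes$y[match(.data$from, nodes$node)],
    xend = nodes$x[match(.data$to, nodes$node)],
    yend = nodes$y[match(.data$to, nodes$node)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$community), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::theme_void()
}
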