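#' Construct an attributed network
#'
#' An attributed network is an undirected simple graph whose nodes each carry a
#' fixed-length vector of categorical attribute values. The graph is the
#' substrate for all coupled-similarity computations: attribute value
#' frequencies, value co-occurrence across attributes, and the consistency
#' between attribute values and edges are all read off this object.
#'
#' @param edges A data frame whose first two columns give the endpoints of each
#'   edge (one row per edge), or `NULL`/zero rows for an edgeless graph. Any
#'   further columns are ignored.
#' @param attributes A data frame with one row per node. The node identifier is
#'   taken from a column named `node` if present, otherwise from the first
#'   column; every remaining column is a categorical attribute. Values are
#'   coerced to character.
#' @param mode Validation mode. `"strict"` (default) rejects self-loops and
#'   duplicate edges with an error; `"lenient"` drops them with a warning. The
#'   strict default reflects the modelling assumption of a simple undirected
#'   graph.
#' @return An object of class `attributed_graph` with components `nodes`
#'   (character vector, defining the stable internal node order), `edges`
#'   (integer matrix, one row per edge, columns indexing `nodes`, smaller index
#'   first), `attributes` (tibble of categorical columns aligned with `nodes`)
#'   and `domains` (list of sorted distinct values per attribute).
#' @examples
#' toy <- toy_fixture()
#' g <- toy$graph
#' g
#' node_attributes(g)
#' @export
attributed_graph <- function(edges, attributes, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(attributes), nrow(attributes) >= 1L)

  attributes <- tibble::as_tibble(attributes)
  id_col <- if ("node" %in% names(attributes)) "node" else names(attributes)[1L]
  nodes <- as.character(attributes[[id_col]])
  if (anyNA(nodes) || any(!nzchar(nodes))) {
    stop("attribute table contains a missing or empty node identifier", call. = FALSE)
  }
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers in the attribute table: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "), call. = FALSE)
  }
  attr_tbl <- attributes[setdiff(names(attributes), id_col)]
  if (ncol(attr_tbl) < 1L) {
    stop("attribute table must contain at least one attribute column", call. = FALSE)
  }
  attr_tbl <- dplyr::mutate(attr_tbl, dplyr::across(dplyr::everything(), as.character))
  for (a in names(attr_tbl)) {
    bad <- is.na(attr_tbl[[a]]) | !nzchar(attr_tbl[[a]])
    if (any(bad)) {
      stop("attribute '", a, "' has a missing/empty value for node(s): ",
           paste(utils::head(nodes[bad], 5L), collapse = ", "), call. = FALSE)
    }
  }

  edge_mat <- matrix(integer(0), ncol = 2L)
  if (!is.null(edges) && nrow(as.data.frame(edges)) > 0L) {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L) stop("edge table needs two endpoint columns", call. = FALSE)
    u <- as.character(edges[[1L]])
    v <- as.character(edges[[2L]])
    iu <- match(u, nodes)
    iv <- match(v, nodes)
    missing_nodes <- unique(c(u[is.na(iu)], v[is.na(iv)]))
    if (length(missing_nodes)) {
      stop("edge endpoint(s) absent from the attribute table: ",
           paste(utils::head(missing_nodes, 5L), collapse = ", "), call. = FALSE)
    }
    edge_mat <- cbind(pmin(iu, iv), pmax(iu, iv))
    loops <- edge_mat[, 1L] == edge_mat[, 2L]
    dups <- duplicated(paste(edge_mat[, 1L], edge_mat[, 2L]))
    if (mode == "strict") {
      if (any(loops)) stop("self-loop(s) on node(s): ",
                           paste(unique(nodes[edge_mat[loops, 1L]]), collapse = ", "),
                           call. = FALSE)
      if (any(dups)) stop(sum(dups), " duplicate edge(s); use mode = \"lenient\" to drop them",
                          call. = FALSE)
    } else if (any(loops | dups)) {
      warning("dropped ", sum(loops), " self-loop(s) and ", sum(dups & !loops),
              " duplicate edge(s)", call. = FALSE)
      edge_mat <- edge_mat[!(loops | dups), , drop = FALSE]
    }
  }
  storage.mode(edge_mat) <- "integer"

  structure(
    list(
      nodes = nodes,
      edges = edge_mat,
      attributes = attr_tbl,
      domains = lapply(attr_tbl, function(x) sort(unique(x)))
    ),
    class = "attributed_graph"
  )
}

#' @export
print.attributed_graph <- function(x, ...) {
  cat("<attributed_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", ncol(x$attributes), " attribute(s): ",
      paste(names(x$attributes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Numbers of nodes, edges and attributes
#'
#' @param g An `attributed_graph`.
#' @return A single integer.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
n_attributes <- function(g) ncol(g$attributes)

#' Edge list and attribute table as tibbles
#'
#' @param g An `attributed_graph`.
#' @return `edge_table()`: a tibble with columns `from`, `to` (node
#'   identifiers, one row per undirected edge). `node_attributes()`: a tibble
#'   with a `node` column followed by the attribute columns.
#' @export
edge_table <- function(g) {
  tibble::tibble(from = g$nodes[g$edges[, 1L]], to = g$nodes[g$edges[, 2L]])
}

#' @rdname edge_table
#' @export
node_attributes <- function(g) {
  dplyr::bind_cols(tibble::tibble(node = g$nodes), g$attributes)
}

# adjacency list of integer neighbour indices, stable node order
adjacency_list <- function(g) {
  n <- length(g$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(g$edges)) {
    e <- g$edges
    adj <- lapply(seq_len(n), function(i) {
      sort(c(e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L]))
    })
  }
  adj
}

node_index <- function(g, id) {
  i <- match(as.character(id), g$nodes)
  if (anyNA(i)) stop("unknown node(s): ", paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

attr_index <- function(g, attribute) {
  if (is.numeric(attribute)) {
    a <- as.integer(attribute)
    if (a < 1L || a > ncol(g$attributes)) stop("attribute index out of range", call. = FALSE)
    return(a)
  }
  a <- match(attribute, names(g$attributes))
  if (is.na(a)) stop("unknown attribute: ", attribute, call. = FALSE)
  a
}

check_value <- function(g, a, x) {
  if (!x %in% g$domains[[a]]) {
    stop("value '", x, "' is not in the domain of attribute '",
         names(g$attributes)[a], "'", call. = FALSE)
  }
  invisible(x)
}

#' Read an attributed network from an edge list and attribute table
#'
#' The edge list is plain text with two whitespace- or tab-separated node
#' identifiers per line (blank lines and `#` comments are skipped; an empty
#' file yields an edgeless graph). The attribute table is delimited text (tab
#' or comma, sniffed from the header) with a header row naming the attributes
#' and one row per node.
#'
#' @param edge_file Path to the edge list.
#' @param attribute_file Path to the node attribute table.
#' @inheritParams attributed_graph
#' @return An `attributed_graph`.
#' @export
read_attributed_network <- function(edge_file, attribute_file,
                                    mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  lines <- readLines(edge_file, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("cannot parse edge list '", edge_file, "' at line ", keep[bad[1L]],
         ": expected two node identifiers, got \"", lines[keep[bad[1L]]], "\"",
         call. = FALSE)
  }
  edges <- if (length(parts)) {
    data.frame(from = vapply(parts, `[`, "", 1L), to = vapply(parts, `[`, "", 2L))
  } else NULL

  header <- readLines(attribute_file, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else " "
  attrs <- readr::read_delim(attribute_file, delim = delim, trim_ws = TRUE,
                             col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE, show_col_types = FALSE)
  attributed_graph(edges, attrs, mode = mode)
}

#' Reduce a raw edge table to an undirected simple edge list
#'
#' Utility for networks recorded as directed and/or weighted relations: the
#' direction is dropped, parallel edges are collapsed to a single edge,
#' self-loops are removed and any weight column is discarded. The result feeds
#' [attributed_graph()] directly.
#'
#' @param edges Data frame whose first two columns are the edge endpoints.
#' @return A tibble with columns `from`, `to`, one row per surviving edge.
#' @export
simplify_edges <- function(edges) {
  edges <- as.data.frame(edges)
  u <- as.character(edges[[1L]])
  v <- as.character(edges[[2L]])
  keep <- u != v
  a <- pmin(u[keep], v[keep])
  b <- pmax(u[keep], v[keep])
  out <- tibble::tibble(from = a, to = b)
  dplyr::distinct(out)
}

#' Convert to an igraph object
#'
#' @param g An `attributed_graph` or `weighted_graph`.
#' @return An [igraph][igraph::graph_from_data_frame] graph carrying the node
#'   attributes (and edge weights for a `weighted_graph`).
#' @export
as_igraph <- function(g) {
  if (inherits(g, "weighted_graph")) {
    el <- tibble::tibble(from = g$nodes[g$edges[, 1L]],
                         to = g$nodes[g$edges[, 2L]],
                         weight = g$weights)
    return(igraph::graph_from_data_frame(el, directed = FALSE,
                                         vertices = data.frame(name = g$nodes)))
  }
  stopifnot(inherits(g, "attributed_graph"))
  igraph::graph_from_data_frame(edge_table(g), directed = FALSE,
                                vertices = as.data.frame(node_attributes(g)))
}

#' Export a weighted graph as GraphML
#'
#' @param w A `weighted_graph`.
#' @param path Output file.
#' @export
write_graphml <- function(w, path) {
  igraph::write_graph(as_igraph(w), path, format = "graphml")
  invisible(path)
}

# ---- partitions -------------------------------------------------------------

#' Partitions of the node set
#'
#' A partition assigns every node to exactly one community. Throughout the
#' package partitions are plain tibbles with columns `node` and `community`;
#' `as_partition()` also accepts a named vector or factor and normalises it.
#' Community labels are opaque: all quality metrics are invariant to
#' relabelling.
#'
#' @param x A tibble/data frame with columns `node` and `community`, or a
#'   vector of community labels named by node.
#' @return A tibble with character `node` and character `community`.
#' @export
as_partition <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("node", "community") %in% names(x)))
    out <- tibble::tibble(node = as.character(x$node),
                          community = as.character(x$community))
  } else {
    stopifnot(!is.null(names(x)))
    out <- tibble::tibble(node = names(x), community = as.character(unname(x)))
  }
  if (anyDuplicated(out$node)) stop("a node appears twice in the partition", call. = FALSE)
  out
}

# integer membership vector aligned with g$nodes
membership_vector <- function(g, partition) {
  p <- as_partition(partition)
  m <- p$community[match(g$nodes, p$node)]
  if (anyNA(m)) stop("partition does not cover every node", call. = FALSE)
  as.integer(factor(m, levels = unique(m)))
}

#' Write / read a partition as two-column TSV
#'
#' Files carry a `node<TAB>community` header followed by one line per node in
#' a deterministic (sorted) node order; an empty partition writes the header
#' only.
#'
#' @param p A partition (see [as_partition()]).
#' @param path File path.
#' @return `read_partition()` returns a partition tibble.
#' @export
write_partition <- function(p, path) {
  p <- if (is.data.frame(p) && nrow(p) == 0L) {
    tibble::tibble(node = character(0), community = character(0))
  } else as_partition(p)
  p <- dplyr::arrange(p, .data$node)
  readr::write_tsv(p, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

# ---- weighted graphs --------------------------------------------------------

#' Construct a weighted graph
#'
#' A symmetric nonnegatively weighted graph whose support is restricted to the
#' adjacency of the underlying plain graph: weights exist only where an edge
#' exists. This is the object SLPA, BGLL and the modularity computation
#' consume.
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Integer matrix (rows = edges, two columns of node indices) or a
#'   data frame of endpoint identifiers.
#' @param weights Numeric vector of nonnegative edge weights, one per edge.
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(nodes, edges, weights) {
  nodes <- as.character(nodes)
  if (is.data.frame(edges)) {
    iu <- match(as.character(edges[[1L]]), nodes)
    iv <- match(as.character(edges[[2L]]), nodes)
    if (anyNA(iu) || anyNA(iv)) stop("edge endpoint not among nodes", call. = FALSE)
    edges <- cbind(pmin(iu, iv), pmax(iu, iv))
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  weights <- as.numeric(weights)
  stopifnot(nrow(edges) == length(weights))
  if (any(weights < 0)) stop("edge weights must be nonnegative", call. = FALSE)
  if (nrow(edges) && any(edges[, 1L] == edges[, 2L])) stop("self-loops not allowed", call. = FALSE)
  structure(list(nodes = nodes, edges = edges, weights = weights),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("<weighted_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " weighted edges, total weight ", format(sum(x$weights)), "\n", sep = "")
  invisible(x)
}

#' Weighted degree (strength) and total weight
#'
#' `node_strength()` returns the per-node sum of incident edge weights;
#' `total_weight()` returns the ordered-pair total, i.e. twice the sum of edge
#' weights — the normaliser of the weighted modularity.
#'
#' @param w A `weighted_graph`.
#' @return A named numeric vector / a single number.
#' @export
node_strength <- function(w) {
  s <- numeric(length(w$nodes))
  if (nrow(w$edges)) {
    add <- rowsum(c(w$weights, w$weights), c(w$edges[, 1L], w$edges[, 2L]))
    s[as.integer(rownames(add))] <- add[, 1L]
  }
  names(s) <- w$nodes
  s
}

#' @rdname node_strength
#' @export
total_weight <- function(w) 2 * sum(w$weights)

#' Write / read weighted edges as three-column TSV
#'
#' One line per unordered edge, `from<TAB>to<TAB>weight`, weights printed with
#' a configurable number of decimal places.
#'
#' @param w A `weighted_graph`.
#' @param path File path.
#' @param digits Decimal places for the weight column.
#' @return `read_weighted_edges()` returns a tibble `from`, `to`, `weight`.
#' @export
write_weighted_edges <- function(w, path, digits = 6) {
  tbl <- tibble::tibble(
    from = w$nodes[w$edges[, 1L]],
    to = w$nodes[w$edges[, 2L]],
    weight = formatC(w$weights, format = "f", digits = digits)
  )
  tbl <- dplyr::arrange(tbl, .data$from, .data$to)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_weighted_edges
#' @export
read_weighted_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    from = readr::col_character(), to = readr::col_character(),
    weight = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
}
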