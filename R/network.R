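NODE_SHAPES <- c(mRNA = "circle", miRNA = "triangle", lncRNA = "diamond")
EDGE_RELATIONS <- c(lnc_mi = "lnc_mi", mi_m = "mi_m", ceRNA = "ceRNA")

#' Assemble the tripartite ceRNA network
#'
#' Nodes are the lncRNAs, mRNAs and miRNAs that appear in passing competing
#' pairs; edges come in three types: `lnc_mi` (miRNA targets the lncRNA),
#' `mi_m` (miRNA targets the mRNA) and `ceRNA` (the competing lncRNA-mRNA
#' pair, carrying the pair statistics). Only the miRNAs shared by a pair
#' are drawn into that pair's neighbourhood, so every competing edge is
#' backed by at least one lncRNA-miRNA-mRNA path. Node attributes include
#' the differential-expression call and the conventional Cytoscape shape
#' (circle = mRNA, triangle = miRNA, diamond = lncRNA).
#'
#' @param pairs A `cerna_pairs` tibble (only rows with `passed == TRUE` are
#'   used).
#' @param de_calls Optional tibble with columns `id`, `call` supplying
#'   up/down annotations; unknown ids get `"not_de"`.
#' @param params Optional [cerna_params()] recorded as provenance.
#' @return A list of class `cerna_network` with elements `nodes` (tibble:
#'   `id`, `type`, `de_call`, `shape`), `edges` (tibble: `from`, `to`,
#'   `relation`, plus pair statistics on `ceRNA` edges), `params`, and
#'   `summary` (node/edge counts by type).
#' @export
build_network <- function(pairs, de_calls = NULL, params = NULL) {
  stopifnot(is.data.frame(pairs))
  use <- pairs[isTRUE_v(pairs$passed), , drop = FALSE]
  nodes <- tibble::tibble(id = character(0), type = character(0))
  edges <- tibble::tibble(from = character(0), to = character(0),
                          relation = character(0))
  if (nrow(use) > 0L) {
    shared <- stringr::str_split(use$shared_mirnas, stringr::fixed(";"))
    mi_ids <- unique(unlist(shared, use.names = FALSE))
    nodes <- dplyr::bind_rows(
      tibble::tibble(id = unique(use$lncrna_id), type = "lncRNA"),
      tibble::tibble(id = mi_ids, type = "miRNA"),
      tibble::tibble(id = unique(use$mrna_id), type = "mRNA"))
    clash <- nodes$id[duplicated(nodes$id)]
    if (length(clash) > 0L) {
      stop("id used with more than one node type: ",
           paste(unique(clash), collapse = ", "), call. = FALSE)
    }
    inter_edges <- purrr::pmap(
      list(use$lncrna_id, use$mrna_id, shared),
      function(l, m, mis) {
        dplyr::bind_rows(
          tibble::tibble(from = l, to = mis, relation = "lnc_mi"),
          tibble::tibble(from = mis, to = m, relation = "mi_m"))
      })
    ce_edges <- tibble::tibble(
      from = use$lncrna_id, to = use$mrna_id, relation = "ceRNA",
      k = use$k, hypergeom_p = use$hypergeom_p,
      hypergeom_fdr = use$hypergeom_fdr, pearson_r = use$pearson_r,
      regime = use$regime)
    edges <- dplyr::bind_rows(dplyr::bind_rows(inter_edges), ce_edges)
    edges <- dplyr::distinct(edges, .data$from, .data$to, .data$relation,
                             .keep_all = TRUE)
    edges <- dplyr::arrange(edges, .data$relation, .data$from, .data$to)
    nodes <- dplyr::arrange(nodes, match(.data$type, names(NODE_SHAPES)),
                            .data$id)
  }
  if (!is.null(de_calls)) {
    nodes <- dplyr::left_join(nodes,
                              dplyr::distinct(tibble::as_tibble(de_calls)[, c("id", "call")]),
                              by = "id")
    nodes$de_call <- dplyr::coalesce(nodes$call, "not_de")
    nodes$call <- NULL
  } else {
    nodes$de_call <- rep("not_de", nrow(nodes))
  }
  nodes$shape <- unname(NODE_SHAPES[nodes$type])
  net <- structure(list(nodes = nodes, edges = edges,
                        params = params,
                        summary = network_summary_counts(nodes, edges)),
                   class = "cerna_network")
  assert_tripartite(net)
  net
}

isTRUE_v <- function(x) !is.na(x) & x

network_summary_counts <- function(nodes, edges) {
  list(
    n_nodes = nrow(nodes),
    n_edges = nrow(edges),
    nodes_by_type = as.list(table(factor(nodes$type,
                                         levels = names(NODE_SHAPES)))),
    edges_by_relation = as.list(table(factor(edges$relation,
                                             levels = EDGE_RELATIONS)))
  )
}

# the type pattern every edge must respect
assert_tripartite <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (nrow(edges) == 0L) return(invisible(net))
  ty <- stats::setNames(nodes$type, nodes$id)
  if (anyNA(ty[edges$from]) || anyNA(ty[edges$to])) {
    stop("edge endpoint missing from node table", call. = FALSE)
  }
  ok <- (edges$relation == "lnc_mi" & ty[edges$from] == "lncRNA" &
           ty[edges$to] == "miRNA") |
    (edges$relation == "mi_m" & ty[edges$from] == "miRNA" &
       ty[edges$to] == "mRNA") |
    (edges$relation == "ceRNA" & ty[edges$from] == "lncRNA" &
       ty[edges$to] == "mRNA")
  if (!all(ok)) {
    stop("edge violates the tripartite type pattern", call. = FALSE)
  }
  invisible(net)
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- x$summary
  cat("ceRNA network: ", s$n_nodes, " nodes (",
      paste(sprintf("%s=%d", names(s$nodes_by_type),
                    unlist(s$nodes_by_type)), collapse = ", "),
      "), ", s$n_edges, " edges (",
      paste(sprintf("%s=%d", names(s$edges_by_relation),
                    unlist(s$edges_by_relation)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Extract a focus-centred subnetwork
#'
#' Induced subgraph of the focus node and its neighbours within `radius`
#' steps (ignoring edge direction), with all edges among the retained
#' nodes. The returned network's `summary` additionally reports
#' `n_regulating_mirnas` and `n_regulating_lncrnas`: the focus node's
#' direct miRNA and lncRNA neighbours, the counts quoted for gene-centred
#' subnetworks.
#'
#' @param net A `cerna_network`.
#' @param focus_id Node id to centre on.
#' @param radius Neighbourhood radius, default 1.
#' @return A `cerna_network`.
#' @export
extract_subnetwork <- function(net, focus_id, radius = 1) {
  stopifnot(inherits(net, "cerna_network"))
  if (!focus_id %in% net$nodes$id) {
    stop("unknown focus node: ", focus_id, call. = FALSE)
  }
  keep <- focus_id
  frontier <- focus_id
  r <- 0L
  while (r < radius && length(frontier) > 0L) {
    nb <- c(net$edges$to[net$edges$from %in% frontier],
            net$edges$from[net$edges$to %in% frontier])
    frontier <- setdiff(unique(nb), keep)
    keep <- union(keep, frontier)
    r <- r + 1L
  }
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ,
                     drop = FALSE]
  direct <- unique(c(net$edges$to[net$edges$from == focus_id],
                     net$edges$from[net$edges$to == focus_id]))
  ty <- stats::setNames(net$nodes$type, net$nodes$id)
  out <- structure(list(nodes = nodes, edges = edges, params = net$params,
                        summary = c(network_summary_counts(nodes, edges),
                                    list(focus = focus_id,
                                         n_regulating_mirnas =
                                           sum(ty[direct] == "miRNA"),
                                         n_regulating_lncrnas =
                                           sum(ty[direct] == "lncRNA")))),
                   class = "cerna_network")
  assert_tripartite(out)
  out
}

#' Export a ceRNA network
#'
#' * `sif`: one line per edge, `source<TAB>relation<TAB>target`, relation
#'   in `lnc_mi`, `mi_m`, `ceRNA` (Cytoscape simple interaction format).
#' * `graphml`: full node attributes (`type`, `de_call`, `shape`) and edge
#'   relations, via igraph.
#' * `tsv`: the edge table with all statistics columns.
#'
#' @param net A `cerna_network`.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "cerna_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$relation,
                     net$edges$to)
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path, progress = FALSE)
  }
  invisible(path)
}

#' Convert a `cerna_network` to an igraph object
#'
#' @param net A `cerna_network`.
#' @return A directed igraph graph with node attributes `type`, `de_call`,
#'   `shape` and edge attribute `relation`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  ed <- as.data.frame(net$edges[, c("from", "to", "relation")])
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = as.data.frame(net$nodes))
}

#' Import a network exported by [export_network()]
#'
#' GraphML imports recover node types and attributes; SIF imports recover
#' node and edge sets, with node types inferred from the edge relations.
#'
#' @param path File path.
#' @param format `"sif"` or `"graphml"`.
#' @return A `cerna_network`.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::tibble(
      id = igraph::vertex_attr(g, "name"),
      type = igraph::vertex_attr(g, "type"),
      de_call = igraph::vertex_attr(g, "de_call"),
      shape = igraph::vertex_attr(g, "shape"))
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(from = el$from, to = el$to,
                            relation = el$relation)
  } else {
    tb <- readr::read_tsv(path, col_names = c("from", "relation", "to"),
                          col_types = "ccc", progress = FALSE)
    edges <- tibble::as_tibble(tb[, c("from", "to", "relation")])
    # infer types from the relation pattern
    ids <- unique(c(edges$from, edges$to))
    ty <- stats::setNames(rep(NA_character_, length(ids)), ids)
    ty[edges$from[edges$relation %in% c("lnc_mi", "ceRNA")]] <- "lncRNA"
    ty[edges$to[edges$relation == "lnc_mi"]] <- "miRNA"
    ty[edges$from[edges$relation == "mi_m"]] <- "miRNA"
    ty[edges$to[edges$relation %in% c("mi_m", "ceRNA")]] <- "mRNA"
    nodes <- tibble::tibble(id = ids, type = unname(ty),
                            de_call = "not_de",
                            shape = unname(NODE_SHAPES[unname(ty)]))
  }
  nodes <- dplyr::arrange(nodes, match(.data$type, names(NODE_SHAPES)),
                          .data$id)
  edges <- dplyr::arrange(edges, .data$relation, .data$from, .data$to)
  net <- structure(list(nodes = nodes, edges = edges, params = NULL,
                        summary = network_summary_counts(nodes, edges)),
                   class = "cerna_network")
  assert_tripartite(net)
  net
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ceRNA network into its edge table
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.cerna_network <- function(x, ...) tibble::as_tibble(x$edges)

#' One-row network summary
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return A one-row tibble of node/edge counts by type.
#' @export
glance.cerna_network <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_nodes = s$n_nodes, n_edges = s$n_edges,
    n_lncrna = s$nodes_by_type$lncRNA, n_mirna = s$nodes_by_type$miRNA,
    n_mrna = s$nodes_by_type$mRNA,
    n_lnc_mi = s$edges_by_relation$lnc_mi,
    n_mi_m = s$edges_by_relation$mi_m,
    n_cerna = s$edges_by_relation$ceRNA)
}

#' Plot a ceRNA network
#'
#' Fruchterman-Reingold layout with the conventional shape/colour coding:
#' circles for mRNA, triangles for miRNA, diamonds for lncRNA.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cerna_network <- function(object, ...) {
  if (nrow(object$nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty network"))
  }
  g <- as_igraph(object)
  set.seed(1L)  # layout reproducibility only
  xy <- igraph::layout_with_fr(g)
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- dplyr::left_join(object$edges,
                         stats::setNames(nd[, c("id", "x", "y")],
                                         c("from", "x0", "y0")),
                         by = "from")
  ed <- dplyr::left_join(ed, stats::setNames(nd[, c("id", "x", "y")],
                                             c("to", "x1", "y1")),
                         by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linetype = .data$relation),
                          colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type,
                                     colour = .data$type), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(mRNA = 16, miRNA = 17,
                                           lncRNA = 18)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
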