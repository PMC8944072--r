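#' Typed protein-protein interaction networks
#'
#' A `ppi_network` is an undirected graph over normalized gene identifiers
#' whose edges carry one of three interaction types: `"physical"`,
#' `"functional"`, or `"both"` (supported by a physical and a functional
#' interaction). There are no self-loops and one record per unordered gene
#' pair; duplicate input rows are collapsed, and a pair reported as both
#' physical and functional is promoted to type `"both"`.
#'
#' @param edges A data frame whose first two columns are gene identifiers;
#'   an optional `type` column (third column) holds the edge type. Missing
#'   types default to `type_default`.
#' @param name Label for the network.
#' @param case_fold Upper-case identifiers? See [normalize_ids()].
#' @param type_default Edge type used when the input has no type column.
#' @return A `ppi_network` object.
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C"),
#'                               type = c("physical", "functional")))
#' network_summary(net)
#' @export
ppi_network <- function(edges, name = "network", case_fold = TRUE,
                        type_default = "functional") {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) abort("`edges` needs at least two identifier columns")
  tbl <- tibble(
    gene_a = normalize_ids(edges[[1L]], case_fold),
    gene_b = normalize_ids(edges[[2L]], case_fold),
    type = if ("type" %in% names(edges)) {
      as.character(edges[["type"]])
    } else if (ncol(edges) >= 3L && is.character(edges[[3L]])) {
      edges[[3L]]
    } else {
      type_default
    }
  )
  bad <- which(!tbl$type %in% EDGE_TYPES)
  if (length(bad) > 0L) {
    abort(sprintf(
      "unknown edge type '%s' in row %d (%s-%s); expected one of %s",
      tbl$type[bad[1L]], bad[1L], tbl$gene_a[bad[1L]], tbl$gene_b[bad[1L]],
      paste(EDGE_TYPES, collapse = "/")))
  }

  all_endpoints <- unique(c(tbl$gene_a, tbl$gene_b))
  n_loops <- sum(tbl$gene_a == tbl$gene_b)
  if (n_loops > 0L) {
    inform(sprintf("dropped %d self-loop(s)", n_loops))
    tbl <- filter(tbl, .data$gene_a != .data$gene_b)
  }
  # canonical unordered orientation, then collapse duplicates
  flip <- tbl$gene_a > tbl$gene_b
  tmp <- tbl$gene_a[flip]
  tbl$gene_a[flip] <- tbl$gene_b[flip]
  tbl$gene_b[flip] <- tmp
  n_in <- nrow(tbl)
  tbl <- tbl |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(type = resolve_types(.data$type), .groups = "drop") |>
    arrange(.data$gene_a, .data$gene_b)
  n_dup <- n_in - nrow(tbl)
  if (n_dup > 0L) inform(sprintf("collapsed %d duplicate edge record(s)", n_dup))

  nodes <- sort(all_endpoints)
  g <- igraph::graph_from_data_frame(tbl, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(
    list(graph = g, edges = tbl, nodes = nodes, name = name,
         csr = build_csr(tbl, nodes),
         dropped = list(self_loops = n_loops, duplicates = n_dup)),
    class = "ppi_network")
}

# compressed sparse adjacency over 0-based node indices, both directions
build_csr <- function(edge_tbl, nodes) {
  n <- length(nodes)
  ia <- match(edge_tbl$gene_a, nodes) - 1L
  ib <- match(edge_tbl$gene_b, nodes) - 1L
  from <- c(ia, ib)
  to <- c(ib, ia)
  ord <- order(from, to)
  list(indptr = c(0L, cumsum(tabulate(from + 1L, nbins = n))),
       indices = to[ord], n_nodes = n)
}

#' @export
print.ppi_network <- function(x, ...) {
  tt <- edge_type_counts(x)
  cat(sprintf("<ppi_network '%s'> %d nodes, %d edges (%d physical, %d functional, %d both)\n",
              x$name, length(x$nodes), nrow(x$edges),
              tt[["physical"]], tt[["functional"]], tt[["both"]]))
  invisible(x)
}

#' @rdname ppi_network
#' @param net A `ppi_network`.
#' @export
network_nodes <- function(net) net$nodes

#' @rdname ppi_network
#' @export
network_edges <- function(net) net$edges

edge_type_counts <- function(net) {
  counts <- table(factor(net$edges$type, levels = EDGE_TYPES))
  setNames(as.integer(counts), EDGE_TYPES)
}

#' Summary statistics of a network
#'
#' @param net A [ppi_network()].
#' @return One-row tibble with node, edge and typed-edge counts and the size
#'   of the largest connected component.
#' @export
network_summary <- function(net) {
  tt <- edge_type_counts(net)
  tibble(network = net$name, n_nodes = length(net$nodes),
         n_edges = nrow(net$edges), physical = tt[["physical"]],
         functional = tt[["functional"]], both = tt[["both"]],
         lcc_size = largest_component(net)$size)
}

#' Read a typed edge list
#'
#' Reads tab-separated edge lists into a [ppi_network()]. The generic
#' dialect expects `geneA <TAB> geneB [<TAB> type]` with `#` comment lines
#' skipped; rows without a type get `type_default`. The `humannet` dialect
#' merges two separately supplied link files (co-functional links in `path`,
#' physical protein-protein interactions in `physical`); pairs present in
#' both files are typed `"both"`. Extra numeric columns (link scores) are
#' ignored.
#'
#' @param path Edge-list file (for `humannet`: the functional link file).
#' @param dialect `"generic"` or `"humannet"`.
#' @param physical Physical link file (required for `dialect = "humannet"`).
#' @param mapping Optional identifier mapping applied at load: a two-column
#'   data frame (or path to a two-column TSV) of source id, gene symbol.
#' @param name,case_fold,type_default Passed to [ppi_network()].
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path, dialect = c("generic", "humannet"),
                           physical = NULL, mapping = NULL,
                           name = NULL, case_fold = TRUE,
                           type_default = "functional") {
  dialect <- match.arg(dialect)
  if (dialect == "humannet") {
    if (is.null(physical)) abort("humannet dialect requires a `physical` link file")
    fn <- read_raw_pairs(path)
    ph <- read_raw_pairs(physical)
    fn_key <- pair_key(fn)
    ph_key <- pair_key(ph)
    both <- fn_key %in% ph_key
    ph_only <- !ph_key %in% fn_key
    edges <- rbind(
      data.frame(a = fn[[1L]], b = fn[[2L]],
                 type = ifelse(both, "both", "functional"),
                 stringsAsFactors = FALSE),
      data.frame(a = ph[[1L]][ph_only], b = ph[[2L]][ph_only],
                 type = rep("physical", sum(ph_only)),
                 stringsAsFactors = FALSE))
  } else {
    raw <- read_raw_pairs(path, keep_type = TRUE)
    edges <- data.frame(a = raw[[1L]], b = raw[[2L]],
                        type = if (ncol(raw) >= 3L) raw[[3L]] else type_default)
    edges$type[is.na(edges$type) | edges$type == ""] <- type_default
  }
  if (!is.null(mapping)) {
    if (is.character(mapping)) {
      mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                   comment.char = "#", stringsAsFactors = FALSE)
    }
    map <- setNames(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
    hit_a <- edges$a %in% names(map)
    hit_b <- edges$b %in% names(map)
    edges$a[hit_a] <- map[edges$a[hit_a]]
    edges$b[hit_b] <- map[edges$b[hit_b]]
  }
  ppi_network(edges, name = name %||% basename(path), case_fold = case_fold,
              type_default = type_default)
}

read_raw_pairs <- function(path, keep_type = FALSE) {
  if (!file.exists(path)) abort(sprintf("cannot read edge list '%s'", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE,
                           quote = "")
  if (ncol(raw) < 2L) abort(sprintf("'%s': need >= 2 tab-separated columns", path))
  if (keep_type && ncol(raw) >= 3L) {
    typ <- raw[[3L]]
    nonempty <- !is.na(typ) & typ != ""
    bad <- which(nonempty & !typ %in% EDGE_TYPES)
    if (length(bad) > 0L) {
      abort(sprintf("'%s': unknown edge-type token '%s' on data line %d",
                    path, typ[bad[1L]], bad[1L]))
    }
    return(raw[, 1:3])
  }
  raw[, 1:2]
}

pair_key <- function(df, case_fold = TRUE) {
  a <- normalize_ids(df[[1L]], case_fold)
  b <- normalize_ids(df[[2L]], case_fold)
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Write a network as a tab-separated typed edge list
#'
#' @param net A [ppi_network()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path, col_names = FALSE)
  invisible(path)
}

#' Largest connected component
#'
#' `largest_component()` returns the maximum-cardinality connected component
#' of the whole network; `induced_lcc()` restricts first to the subgraph
#' induced by `genes` (identifiers absent from the network are ignored with
#' a logged count).
#'
#' @param net A [ppi_network()].
#' @return A `component_view`: a list with `members` (sorted gene
#'   identifiers), `size`, and `network` (the parent network's name).
#' @export
largest_component <- function(net) {
  induced_component(net, seq_along(net$nodes) - 1L)
}

#' @rdname largest_component
#' @param genes Character vector of gene identifiers.
#' @export
induced_lcc <- function(net, genes) {
  genes <- unique(normalize_ids(genes))
  idx <- match(genes, net$nodes)
  n_miss <- sum(is.na(idx))
  if (n_miss > 0L) inform(sprintf("%d gene(s) not in network ignored", n_miss))
  induced_component(net, idx[!is.na(idx)] - 1L)
}

induced_component <- function(net, idx0) {
  if (length(idx0) == 0L) {
    members <- character(0)
  } else {
    mem0 <- cpp_lcc_members(net$csr$indptr, net$csr$indices,
                            as.integer(idx0), net$csr$n_nodes)
    members <- sort(net$nodes[mem0 + 1L])
  }
  structure(list(members = members, size = length(members),
                 network = net$name),
            class = "component_view")
}

#' @export
print.component_view <- function(x, ...) {
  cat(sprintf("<component_view> %d genes (network '%s')\n", x$size, x$network))
  if (x$size > 0L) cat(" ", paste(head(x$members, 8L), collapse = ", "),
                       if (x$size > 8L) "..." else "", "\n")
  invisible(x)
}

#' @rdname largest_component
#' @param x A `component_view`.
#' @export
component_members <- function(x) x$members

#' Export an induced subnetwork with annotations
#'
#' Writes the subgraph induced by `genes` to GraphML (`<path>.graphml`) and
#' to a typed tab-separated edge list (`<path>.tsv`). Node annotations
#' (e.g. module membership, disease-gene flags) are taken from the
#' `annotations` table and augmented with each node's degree within the
#' exported subnetwork; genes missing from `annotations` get empty labels
#' with a warning.
#'
#' @param net A [ppi_network()].
#' @param genes Nonempty character vector of genes to keep.
#' @param annotations Optional data frame with a `gene` column plus label
#'   columns.
#' @param path Output path prefix (no extension).
#' @return Invisibly, a list with the two file paths and the node table.
#' @export
export_subnetwork <- function(net, genes, annotations = NULL, path) {
  genes <- unique(normalize_ids(genes))
  if (length(genes) == 0L) abort("`genes` must be nonempty")
  keep <- intersect(genes, net$nodes)
  sub_edges <- filter(net$edges, .data$gene_a %in% keep & .data$gene_b %in% keep)
  deg <- table(factor(c(sub_edges$gene_a, sub_edges$gene_b), levels = keep))
  node_tbl <- tibble(gene = keep, degree_in_subnetwork = as.integer(deg[keep]))
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    annotations$gene <- normalize_ids(annotations$gene)
    missing <- setdiff(keep, annotations$gene)
    if (length(missing) > 0L) {
      warn(sprintf("%d gene(s) lack annotations; exported with empty labels",
                   length(missing)))
    }
    node_tbl <- left_join(node_tbl, annotations, by = "gene")
    for (col in setdiff(names(node_tbl), c("gene", "degree_in_subnetwork"))) {
      if (is.character(node_tbl[[col]])) {
        node_tbl[[col]][is.na(node_tbl[[col]])] <- ""
      }
    }
  }
  g <- igraph::graph_from_data_frame(sub_edges, directed = FALSE,
                                     vertices = as.data.frame(node_tbl))
  graphml <- paste0(path, ".graphml")
  tsv <- paste0(path, ".tsv")
  igraph::write_graph(g, graphml, format = "graphml")
  readr::write_tsv(sub_edges, tsv, col_names = FALSE)
  invisible(list(graphml = graphml, edge_list = tsv, nodes = node_tbl))
}
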