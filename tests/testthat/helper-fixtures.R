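# Shared fixtures and independent oracles, all built in code.

# T1 toy: path A-B-C-D-E with mixed edge types
t1_network <- function() {
  suppressMessages(ppi_network(
    data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "E"),
               type = c("physical", "functional", "both", "functional")),
    name = "t1"))
}

# 5-node star: hub X with leaves Y1..Y4
star_network <- function() {
  suppressMessages(ppi_network(
    data.frame(a = rep("X", 4), b = paste0("Y", 1:4), type = "functional"),
    name = "star"))
}

# Erdos-Renyi network via igraph, wrapped as a ppi_network
random_ppi <- function(n, p = 0.03, seed = 1, name = "rand") {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0L) stop("empty random graph; raise p")
    types <- sample(c("physical", "functional", "both"), nrow(el),
                    replace = TRUE)
    suppressMessages(ppi_network(
      data.frame(a = paste0("N", el[, 1]), b = paste0("N", el[, 2]),
                 type = types), name = name))
  })
}

# Independent component oracle: label components by repeated BFS over an
# adjacency list built directly from the edge table.
oracle_components <- function(net, genes = network_nodes(net)) {
  genes <- intersect(genes, network_nodes(net))
  edges <- network_edges(net)
  edges <- edges[edges$gene_a %in% genes & edges$gene_b %in% genes, ]
  adj <- lapply(setNames(vector("list", length(genes)), genes), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  unvisited <- genes
  comps <- list()
  while (length(unvisited) > 0L) {
    queue <- unvisited[1L]
    comp <- character(0)
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!v %in% comp) {
        comp <- c(comp, v)
        queue <- c(queue, setdiff(adj[[v]], comp))
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    unvisited <- setdiff(unvisited, comp)
  }
  comps
}

oracle_lcc_size <- function(net, genes = network_nodes(net)) {
  if (length(intersect(genes, network_nodes(net))) == 0L) return(0L)
  max(lengths(oracle_components(net, genes)))
}

# Exhaustive null over all C(n, k) subsets: exact mean/sd of induced LCC size
oracle_exhaustive_lcc_null <- function(net, k) {
  nodes <- network_nodes(net)
  sizes <- apply(utils::combn(length(nodes), k), 2L, function(idx) {
    oracle_lcc_size(net, nodes[idx])
  })
  list(mean = mean(sizes), sd = sqrt(mean((sizes - mean(sizes))^2)),
       sizes = sizes)
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
oracle_hypergeom_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d <= K))
  mean(hits >= k)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Exact null moments of induced-LCC size over all C(n, k) subsets, computed
# from the adjacency matrix with a tiny label-propagation component step;
# population sd (denominator n), matching the distribution itself.
fast_exhaustive_lcc_null <- function(net, k) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- network_edges(net)
  A[cbind(e$gene_a, e$gene_b)] <- TRUE
  A[cbind(e$gene_b, e$gene_a)] <- TRUE
  subsets <- utils::combn(n, k)
  sizes <- apply(subsets, 2L, function(s) {
    labels <- seq_len(k)
    sub <- A[s, s, drop = FALSE]
    repeat {
      changed <- FALSE
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          if (sub[i, j] && labels[i] != labels[j]) {
            labels[labels == max(labels[i], labels[j])] <-
              min(labels[i], labels[j])
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    max(tabulate(labels))
  })
  list(mean = mean(sizes), sd = sqrt(mean((sizes - mean(sizes))^2)))
}
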