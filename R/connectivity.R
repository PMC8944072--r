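resolve_shared <- function(a, b, shared = c("exclude", "error")) {
  shared <- match.arg(shared)
  a <- unique(normalize_ids(a))
  b <- unique(normalize_ids(b))
  common <- intersect(a, b)
  if (length(common) > 0L && shared == "error") {
    abort(sprintf("gene sets share %d gene(s): %s", length(common),
                  paste(head(common, 10L), collapse = ", ")))
  }
  list(a = setdiff(a, common), b = setdiff(b, common), shared = common)
}

#' Count edges connecting two gene sets, by type
#'
#' Tallies network edges with one endpoint in `A` and the other in `B`.
#' Genes shared by both sets are excluded before counting (default policy),
#' so a gene is never counted as linking a module to itself; with
#' `shared = "error"` overlapping sets are rejected, naming the shared
#' genes.
#'
#' @param net A [ppi_network()].
#' @param a,b Character vectors of gene identifiers (subsets of the
#'   network's nodes).
#' @param shared Policy for genes in both sets: `"exclude"` (default) or
#'   `"error"`.
#' @return One-row tibble (`total`, `physical`, `functional`, `both`), with
#'   `total = physical + functional + both`.
#' @export
count_inter_module_edges <- function(net, a, b, shared = "exclude") {
  s <- resolve_shared(a, b, shared)
  cross <- filter(net$edges,
                  (.data$gene_a %in% s$a & .data$gene_b %in% s$b) |
                  (.data$gene_a %in% s$b & .data$gene_b %in% s$a))
  tt <- table(factor(cross$type, levels = EDGE_TYPES))
  tibble(total = nrow(cross), physical = as.integer(tt[["physical"]]),
         functional = as.integer(tt[["functional"]]),
         both = as.integer(tt[["both"]]))
}

#' Permutation significance of inter-module connectivity
#'
#' Tests whether two gene sets are connected by more edges than expected by
#' chance. Both sets are jointly resampled as degree-matched surrogates
#' (disjoint within each draw: each degree bin contributes the combined
#' count without replacement), the cross-edge count is recorded per draw,
#' and the observed count is scored by the add-one empirical p-value
#' (greater tail) and a z-score.
#'
#' @inheritParams count_inter_module_edges
#' @param null A [null_model_config()].
#' @param labels Length-2 character vector naming the two sets.
#' @return One-row tibble of class `connectivity_test` with the observed
#'   [count_inter_module_edges()] tally, `null_mean`, `null_sd`, `z_score`,
#'   `empirical_p`, and the null configuration; the full null distribution
#'   is attached as attribute `"null_values"`.
#' @export
inter_module_significance <- function(net, a, b, null = null_model_config(),
                                      shared = "exclude",
                                      labels = c("A", "B")) {
  s <- resolve_shared(a, b, shared)
  sa <- intersect(s$a, net$nodes)
  sb <- intersect(s$b, net$nodes)
  if (length(sa) == 0L || length(sb) == 0L) {
    abort("both gene sets must be nonempty after shared-gene exclusion")
  }
  observed <- count_inter_module_edges(net, sa, sb, shared = "exclude")
  bins <- bins_for(net, null)
  ca <- target_bin_counts(bins, sa)
  cb <- target_bin_counts(bins, sb)
  sizes <- vapply(bins$bin_nodes, length, integer(1))
  if (any(ca + cb > sizes)) {
    abort("insufficient distinct nodes in a degree bin to draw disjoint surrogates")
  }
  csr <- net$csr
  null_counts <- with_seed_if(null$seed,
    cpp_null_cross(csr$indptr, csr$indices, csr$n_nodes, bins$bin_index0,
                   as.integer(ca), as.integer(cb), null$n_samples))
  mu <- mean(null_counts)
  sg <- sd(null_counts)
  out <- tibble(set_a = labels[1L], set_b = labels[2L],
                n_a = length(sa), n_b = length(sb),
                n_shared_excluded = length(s$shared)) |>
    dplyr::bind_cols(observed) |>
    mutate(null_mean = mu, null_sd = sg,
           z_score = ifelse(sg > 0, (.data$total - mu) / sg, NA_real_),
           empirical_p = empirical_p(.data$total, null_counts),
           n_samples = null$n_samples, method = null$method)
  attr(out, "null_values") <- null_counts
  class(out) <- c("connectivity_test", class(out))
  out
}

#' Interactor genes linking modules
#'
#' An interactor is a gene of one module with at least one direct network
#' edge to a gene of another module. For every ordered (home, target) module
#' pair, lists the home-module genes with cross edges into the target
#' (genes shared by the pair are excluded first), their cross-edge counts by
#' type, and whether the gene connects to more than one target module.
#'
#' @param net A [ppi_network()].
#' @param modules Named list (>= 2) of gene-identifier vectors.
#' @param include_unconnected Also emit one `target = "No module"` row for
#'   each module gene with no cross edges to any other module (the layout
#'   used for module tables).
#' @return Tibble with columns `gene`, `home`, `target`, `n_edges`,
#'   `physical`, `functional`, `both`, `multi_target`.
#' @export
find_interactors <- function(net, modules, include_unconnected = FALSE) {
  if (length(modules) < 2L || is.null(names(modules))) {
    abort("`modules` must be a named list of at least two gene sets")
  }
  modules <- lapply(modules, function(g) intersect(unique(normalize_ids(g)),
                                                   net$nodes))
  rows <- list()
  for (home in names(modules)) {
    for (target in setdiff(names(modules), home)) {
      s <- resolve_shared(modules[[home]], modules[[target]], "exclude")
      cross <- filter(net$edges,
                      (.data$gene_a %in% s$a & .data$gene_b %in% s$b) |
                      (.data$gene_a %in% s$b & .data$gene_b %in% s$a))
      if (nrow(cross) == 0L) next
      home_end <- ifelse(cross$gene_a %in% s$a, cross$gene_a, cross$gene_b)
      tal <- tibble(gene = home_end, type = cross$type) |>
        count(.data$gene, .data$type) |>
        tidyr::pivot_wider(names_from = "type", values_from = "n",
                           values_fill = 0L)
      for (ty in EDGE_TYPES) if (!ty %in% names(tal)) tal[[ty]] <- 0L
      rows[[paste(home, target)]] <- tal |>
        mutate(home = home, target = target,
               n_edges = .data$physical + .data$functional + .data$both)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(gene = character(0), home = character(0),
                  target = character(0), n_edges = integer(0),
                  physical = integer(0), functional = integer(0),
                  both = integer(0), multi_target = logical(0))
  } else {
    out <- out |>
      group_by(.data$gene, .data$home) |>
      mutate(multi_target = dplyr::n_distinct(.data$target) > 1L) |>
      ungroup() |>
      select("gene", "home", "target", "n_edges", "physical",
             "functional", "both", "multi_target") |>
      arrange(.data$home, .data$target, .data$gene)
  }
  if (include_unconnected) {
    extra <- purrr::imap(modules, function(genes, home) {
      idle <- setdiff(genes, out$gene[out$home == home])
      if (length(idle) == 0L) return(NULL)
      tibble(gene = idle, home = home, target = "No module",
             n_edges = 0L, physical = 0L, functional = 0L, both = 0L,
             multi_target = FALSE)
    })
    out <- bind_rows(out, bind_rows(extra))
  }
  out
}

#' Summarize interactor counts per module pair
#'
#' @param interactors A [find_interactors()] table.
#' @return Tibble with one row per (home, target) pair: number of interactor
#'   genes and total cross edges.
#' @export
interactor_summary <- function(interactors) {
  interactors |>
    filter(.data$target != "No module") |>
    group_by(.data$home, .data$target) |>
    summarise(n_interactors = n(), n_cross_edges = sum(.data$n_edges),
              .groups = "drop")
}

#' Hypergeometric edge-type composition test
#'
#' Tests whether edges of one type (functional, by default) are
#' over-represented among an observed set of edges, relative to the
#' network-wide edge-type composition: the upper-tail hypergeometric
#' probability of drawing at least `k` edges of the type of interest in
#' `total` draws from the network's edge population. Whether edges typed
#' `"both"` count toward the type of interest is an explicit parameter and
#' is recorded in the output.
#'
#' @param observed A [count_inter_module_edges()] tally (or any list with
#'   `total`, `physical`, `functional`, `both`).
#' @param net A [ppi_network()] providing the edge population.
#' @param type_of_interest Edge type tested for enrichment.
#' @param pool_both Count `"both"` edges as the type of interest?
#' @return One-row tibble: counts, the population partition used, and the
#'   upper-tail `p_value`.
#' @export
edge_type_composition_test <- function(observed, net,
                                       type_of_interest = "functional",
                                       pool_both = FALSE) {
  type_of_interest <- match.arg(type_of_interest, c("functional", "physical"))
  if (observed$total < 1L) abort("`observed$total` must be >= 1")
  pop <- edge_type_counts(net)
  N <- sum(pop)
  K <- pop[[type_of_interest]] + if (pool_both) pop[["both"]] else 0L
  k <- observed[[type_of_interest]] + if (pool_both) observed[["both"]] else 0L
  n_draw <- observed$total
  if (n_draw > N || k > K) abort("observed counts exceed the edge population")
  tibble(type = type_of_interest, pool_both = pool_both,
         k = as.integer(k), n_draws = as.integer(n_draw),
         K_population = as.integer(K), N_population = as.integer(N),
         p_value = phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE))
}

#' Connectivity of a single gene set
#'
#' Scores how connected a gene set is within the network: the observed
#' statistic is the number of edges with both endpoints in the set (default)
#' or the set's induced LCC size (`statistic = "lcc"`); random expectation
#' comes from degree-matched sampled sets of the same size.
#'
#' @param net A [ppi_network()].
#' @param genes Gene identifiers; at least 2 must map to the network.
#' @param null A [null_model_config()].
#' @param statistic `"edges"` (within-set edge count) or `"lcc"`.
#' @return One-row tibble of class `connectivity_test` (see
#'   [inter_module_significance()]); the induced LCC size is reported
#'   alongside either statistic.
#' @export
gene_set_connectivity <- function(net, genes, null = null_model_config(),
                                  statistic = c("edges", "lcc")) {
  statistic <- match.arg(statistic)
  genes <- intersect(unique(normalize_ids(genes)), net$nodes)
  if (length(genes) < 2L) abort("fewer than 2 genes map to the network")
  idx0 <- as.integer(match(genes, net$nodes) - 1L)
  csr <- net$csr
  obs_edges <- cpp_count_within(csr$indptr, csr$indices, csr$n_nodes, idx0)
  obs_lcc <- cpp_lcc_size(csr$indptr, csr$indices, idx0, csr$n_nodes)
  observed <- if (statistic == "edges") obs_edges else obs_lcc
  bins <- bins_for(net, null)
  counts <- as.integer(target_bin_counts(bins, genes))
  null_values <- with_seed_if(null$seed, {
    if (statistic == "edges") {
      cpp_null_within(csr$indptr, csr$indices, csr$n_nodes, bins$bin_index0,
                      counts, null$n_samples)
    } else {
      cpp_null_lcc(csr$indptr, csr$indices, csr$n_nodes, bins$bin_index0,
                   counts, null$n_samples)
    }
  })
  mu <- mean(null_values)
  sg <- sd(null_values)
  out <- tibble(statistic = statistic, n_genes = length(genes),
                observed = observed, within_edges = obs_edges,
                lcc_size = obs_lcc, null_mean = mu, null_sd = sg,
                z_score = ifelse(sg > 0, (observed - mu) / sg, NA_real_),
                empirical_p = empirical_p(observed, null_values),
                n_samples = null$n_samples, method = null$method)
  attr(out, "null_values") <- null_values
  class(out) <- c("connectivity_test", class(out))
  out
}

#' Largest component of a module union
#'
#' The LCC of the subgraph induced by the union of several modules'
#' genes, with per-module membership annotation (genes belonging to several
#' modules carry all labels).
#'
#' @param net A [ppi_network()].
#' @param modules Named list of gene sets.
#' @return Tibble of the component's genes with a comma-separated `module`
#'   label column; the component size is attached as attribute `"size"`.
#' @export
union_component <- function(net, modules) {
  if (length(modules) == 0L) abort("`modules` must be nonempty")
  modules <- lapply(modules, function(g) unique(normalize_ids(g)))
  cv <- induced_lcc(net, unique(unlist(modules)))
  labels <- vapply(cv$members, function(g) {
    paste(names(modules)[vapply(modules, function(m) g %in% m, logical(1))],
          collapse = ",")
  }, character(1))
  out <- tibble(gene = cv$members, module = labels)
  attr(out, "size") <- cv$size
  out
}
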