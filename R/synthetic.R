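#' Synthetic study scenario configuration
#'
#' Parameters for generating a benchmark with the statistical structure the
#' pipeline assumes: a scale-free interactome with typed edges, planted
#' connected gene modules whose members carry small Beta(a, 1) p-values,
#' uniform background p-values, and optional excess edges planted between
#' module pairs. The defaults mirror the study design the package targets:
#' one exposure dataset and two disease datasets over one interactome, with
#' planted module sizes 50, 37 and 64 and edge-type proportions matching a
#' large co-functional interactome (118,012 physical / 213,003 functional /
#' 39,587 both, i.e. roughly 0.318 / 0.573 / 0.107).
#'
#' @param n_nodes Number of network nodes (default 2000).
#' @param m Preferential-attachment parameter: edges added per new node
#'   (default 3).
#' @param type_props Named numeric proportions for edge types; must sum
#'   to 1.
#' @param module_sizes Named integer vector of planted module sizes, one
#'   per dataset.
#' @param signal_a Beta(a, 1) shape for planted-gene p-values, in (0, 1\];
#'   `a = 1` is exactly the uniform null (default 0.1).
#' @param cross_edges Excess functional edges planted between the first
#'   (exposure) module and each disease module (default 40).
#' @param seed Integer seed for the whole scenario.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_nodes = 2000, m = 3,
                            type_props = c(physical = 118012,
                                           functional = 213003,
                                           both = 39587) / 370602,
                            module_sizes = c(exposure_methylation = 50,
                                             disease_methylation = 37,
                                             disease_expression = 64),
                            signal_a = 0.1, cross_edges = 40, seed = 1L) {
  if (abs(sum(type_props) - 1) > 1e-8 || any(type_props < 0)) {
    abort("`type_props` must be nonnegative and sum to 1")
  }
  if (!setequal(names(type_props), EDGE_TYPES)) {
    abort("`type_props` must be named physical/functional/both")
  }
  assert_scalar_number(signal_a, "signal_a", lower = 1e-12, upper = 1)
  if (any(module_sizes < 2) || any(module_sizes > n_nodes)) {
    abort("module sizes must be in [2, n_nodes]")
  }
  structure(list(n_nodes = as.integer(n_nodes), m = as.integer(m),
                 type_props = type_props[EDGE_TYPES],
                 module_sizes = module_sizes, signal_a = signal_a,
                 cross_edges = as.integer(cross_edges),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a scale-free typed network
#'
#' Preferential attachment: the seed graph is a complete graph on `m` nodes
#' (a single node for `m = 1`) and each subsequent node attaches to `m`
#' distinct existing nodes chosen with probability proportional to degree.
#' The result is connected by construction with exactly
#' `m * (n_nodes - m) + choose(m, 2)` edges. Each edge independently
#' receives a type drawn from `type_props`.
#'
#' @inheritParams scenario_config
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A [ppi_network()].
#' @export
generate_network <- function(n_nodes = 2000, m = 3,
                             type_props = c(physical = 118012,
                                            functional = 213003,
                                            both = 39587) / 370602,
                             seed = NULL) {
  if (n_nodes < 10L) abort("`n_nodes` must be at least 10")
  if (m < 1L || m >= n_nodes) abort("need 1 <= m < n_nodes")
  if (abs(sum(type_props) - 1) > 1e-8 || any(type_props < 0)) {
    abort("`type_props` must be nonnegative and sum to 1")
  }
  with_seed_if(seed, {
    deg <- integer(n_nodes)
    from <- integer(0)
    to <- integer(0)
    if (m > 1L) {
      seed_pairs <- utils::combn(m, 2L)
      from <- seed_pairs[1L, ]
      to <- seed_pairs[2L, ]
      deg[1:m] <- m - 1L
    }
    for (v in (m + 1L):n_nodes) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]
      targets <- if (sum(w) == 0) {
        sample(existing, min(m, v - 1L))
      } else {
        sample(existing, min(m, v - 1L), prob = w)
      }
      from <- c(from, targets)
      to <- c(to, rep.int(v, length(targets)))
      deg[targets] <- deg[targets] + 1L
      deg[v] <- deg[v] + length(targets)
    }
    fmt <- paste0("G%0", nchar(as.character(n_nodes)), "d")
    types <- sample(EDGE_TYPES, length(from), replace = TRUE,
                    prob = type_props[EDGE_TYPES])
    suppressMessages(ppi_network(
      data.frame(a = sprintf(fmt, from), b = sprintf(fmt, to), type = types),
      name = sprintf("synthetic_pa_n%d_m%d", n_nodes, m)))
  })
}

#' Plant a random connected module
#'
#' Grows a connected induced gene set: starting from a random eligible node,
#' repeatedly adds a uniformly chosen neighbor of the current set until the
#' requested size is reached. Nodes in `avoid` are never used, so planted
#' modules can be kept disjoint.
#'
#' @param net A [ppi_network()].
#' @param size Module size (at most the LCC size).
#' @param avoid Genes excluded from the module.
#' @param max_tries Restart attempts before giving up.
#' @return Character vector of `size` genes whose induced subgraph is
#'   connected.
#' @export
plant_connected_module <- function(net, size, avoid = character(0),
                                   max_tries = 100L) {
  lcc <- largest_component(net)
  if (size > lcc$size) abort("`size` exceeds the network's LCC")
  candidates <- setdiff(lcc$members, avoid)
  if (length(candidates) < size) abort("not enough eligible nodes")
  adj <- net$csr
  get_nbrs <- function(i0) {
    lo <- adj$indptr[i0 + 1L]
    hi <- adj$indptr[i0 + 2L]
    if (hi <= lo) integer(0) else adj$indices[(lo + 1L):hi]
  }
  avoid_idx <- match(avoid, net$nodes)
  for (try in seq_len(max_tries)) {
    start <- match(sample(candidates, 1L), net$nodes) - 1L
    members <- start
    in_set <- logical(length(net$nodes))
    in_set[start + 1L] <- TRUE
    frontier <- setdiff(get_nbrs(start), c(members, avoid_idx - 1L))
    ok <- TRUE
    while (length(members) < size) {
      frontier <- frontier[!in_set[frontier + 1L]]
      if (length(frontier) == 0L) { ok <- FALSE; break }
      nxt <- frontier[sample.int(length(frontier), 1L)]
      members <- c(members, nxt)
      in_set[nxt + 1L] <- TRUE
      new_nbrs <- get_nbrs(nxt)
      new_nbrs <- new_nbrs[!in_set[new_nbrs + 1L]]
      new_nbrs <- setdiff(new_nbrs, avoid_idx - 1L)
      frontier <- unique(c(frontier, new_nbrs))
    }
    if (ok) return(sort(net$nodes[members + 1L]))
  }
  abort(sprintf("could not grow a connected module of size %d in %d tries",
                size, max_tries))
}

#' Generate planted-signal p-values
#'
#' Planted genes receive `p ~ Beta(a, 1)` (stochastically small for
#' `a < 1`); every other network gene receives `p ~ Uniform(0, 1)`. With
#' `a = 1`, Beta(1, 1) is the uniform distribution and the table is an
#' exact draw from the global null.
#'
#' @param net A [ppi_network()].
#' @param planted Character vector of signal genes.
#' @param a Beta shape in (0, 1\].
#' @param dataset_name Label for the table.
#' @param seed Optional seed.
#' @return A [gene_score_table()] covering every network gene; the planted
#'   set is attached as attribute `"planted"`.
#' @export
generate_scores <- function(net, planted, a = 0.1, dataset_name = "synthetic",
                            seed = NULL) {
  assert_scalar_number(a, "a", lower = 1e-12, upper = 1)
  planted <- unique(normalize_ids(planted))
  with_seed_if(seed, {
    genes <- net$nodes
    p <- runif(length(genes))
    hit <- genes %in% planted
    p[hit] <- rbeta(sum(hit), a, 1)
    tbl <- gene_score_table(tibble(gene = genes, p_value = p),
                            dataset_name = dataset_name)
    attr(tbl, "planted") <- planted
    tbl
  })
}

#' Plant excess edges between two gene sets
#'
#' Adds `extra` uniformly chosen currently-absent pairs between `a` and `b`
#' (shared genes excluded) as functional edges, creating a known
#' inter-module connectivity signal.
#'
#' @param net A [ppi_network()].
#' @param a,b Gene sets.
#' @param extra Number of edges to add (feasible given absent pairs).
#' @param seed Optional seed.
#' @return List with `network` (the augmented [ppi_network()]) and `added`
#'   (tibble of the new edges).
#' @export
plant_cross_edges <- function(net, a, b, extra, seed = NULL) {
  s <- resolve_shared(a, b, "exclude")
  sa <- intersect(s$a, net$nodes)
  sb <- intersect(s$b, net$nodes)
  if (extra == 0L) {
    return(list(network = net,
                added = tibble(gene_a = character(0), gene_b = character(0),
                               type = character(0))))
  }
  pairs <- tidyr::expand_grid(x = sa, y = sb) |>
    mutate(gene_a = pmin(.data$x, .data$y), gene_b = pmax(.data$x, .data$y)) |>
    distinct(.data$gene_a, .data$gene_b)
  existing <- paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")
  absent <- pairs[!paste(pairs$gene_a, pairs$gene_b, sep = "\r") %in% existing, ]
  if (extra > nrow(absent)) {
    abort(sprintf("only %d absent pairs available; cannot add %d",
                  nrow(absent), extra))
  }
  added <- with_seed_if(seed, absent[sample.int(nrow(absent), extra), ]) |>
    mutate(type = "functional")
  new_edges <- bind_rows(net$edges, added)
  net2 <- suppressMessages(ppi_network(
    data.frame(a = new_edges$gene_a, b = new_edges$gene_b,
               type = new_edges$type),
    name = net$name))
  list(network = net2, added = as_tibble(added))
}

#' Generate the full benchmark scenario
#'
#' Builds one network, plants one disjoint connected module per configured
#' dataset, wires the first (exposure) module to each subsequent (disease)
#' module with `cross_edges` planted functional edges, and draws one score
#' table per dataset in which only that dataset's module carries signal.
#' The ground truth (module memberships, planted edges, config) is returned
#' alongside the data.
#'
#' @param config A [scenario_config()].
#' @return A `study_scenario` list: `network`, `scores` (named list of
#'   [gene_score_table()]s), and `truth` (list with `modules`,
#'   `planted_cross_edges`, `config`).
#' @export
generate_study_scenario <- function(config = scenario_config()) {
  withr::with_seed(config$seed, {
    net <- generate_network(config$n_nodes, config$m, config$type_props)
    sizes <- config$module_sizes
    modules <- list()
    used <- character(0)
    for (nm in names(sizes)) {
      modules[[nm]] <- plant_connected_module(net, sizes[[nm]], avoid = used)
      used <- c(used, modules[[nm]])
    }
    added <- list()
    if (length(modules) >= 2L && config$cross_edges > 0L) {
      first <- names(sizes)[1L]
      for (nm in names(sizes)[-1L]) {
        res <- plant_cross_edges(net, modules[[first]], modules[[nm]],
                                 config$cross_edges)
        net <- res$network
        added[[paste(first, nm, sep = "__")]] <- res$added
      }
    }
    scores <- purrr::imap(modules, function(genes, nm) {
      generate_scores(net, genes, a = config$signal_a, dataset_name = nm)
    })
    structure(list(network = net, scores = scores,
                   truth = list(modules = modules,
                                planted_cross_edges = added,
                                config = unclass(config))),
              class = "study_scenario")
  })
}

#' @export
print.study_scenario <- function(x, ...) {
  cat(sprintf("<study_scenario> %d datasets over:\n", length(x$scores)))
  print(x$network)
  invisible(x)
}

#' Write / read a scenario directory
#'
#' Serializes a [generate_study_scenario()] result as plain text: the
#' network edge list, one score table per dataset, and a JSON truth file
#' (module memberships, planted cross edges, config snapshot).
#'
#' @param scenario A `study_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(scenario$network, file.path(dir, "network.tsv"))
  for (nm in names(scenario$scores)) {
    write_score_table(scenario$scores[[nm]],
                      file.path(dir, paste0("scores_", nm, ".tsv")))
  }
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  net <- read_edge_list(file.path(dir, "network.tsv"), name = "network")
  files <- list.files(dir, pattern = "^scores_.*\\.tsv$", full.names = TRUE)
  nms <- sub("^scores_(.*)\\.tsv$", "\\1", basename(files))
  scores <- setNames(lapply(seq_along(files), function(i) {
    read_score_table(files[[i]], dataset_name = nms[[i]])
  }), nms)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(network = net, scores = scores, truth = truth),
            class = "study_scenario")
}

#' Jaccard index of two gene sets
#'
#' @param a,b Character vectors.
#' @return `|a & b| / |a | b|`.
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(NA_real_)
  length(intersect(a, b)) / length(u)
}
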