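#' Pipeline configuration
#'
#' Validated bundle of everything one end-to-end run needs. Inputs may be
#' given as in-memory objects or as file paths; every referenced path must
#' exist at validation time (the run fails fast, before any computation).
#'
#' @param network A [ppi_network()] or an edge-list path.
#' @param scores Named list of [gene_score_table()]s or score-table paths
#'   (names are the dataset labels).
#' @param null A [null_model_config()]. Its seed, when unset, is derived
#'   from `seed`.
#' @param rule A [selection_rule()].
#' @param collections Named list of GMT collections (tibbles or paths) for
#'   enrichment; optional.
#' @param background `"network_lcc"` (default: genes of the network's
#'   largest connected component) or a gene-list path / character vector.
#' @param disease_genes Named list of disease-gene lists (character vectors
#'   or paths); optional.
#' @param robustness_networks Named list of alternative [ppi_network()]s or
#'   edge-list paths; optional.
#' @param out_dir Run directory to create.
#' @param seed Integer master seed; per-stage sub-seeds are derived from it
#'   deterministically and recorded in the manifest.
#' @param dialect Edge-list dialect when `network` is a path.
#' @param max_threshold,max_points Sweep grid settings, see
#'   [make_threshold_grid()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(network, scores, null = null_model_config(),
                            rule = selection_rule(), collections = NULL,
                            background = "network_lcc", disease_genes = NULL,
                            robustness_networks = NULL, out_dir, seed = 1L,
                            dialect = "generic", max_threshold = 0.05,
                            max_points = 60) {
  check_path <- function(x, what) {
    if (is.character(x) && length(x) == 1L && !file.exists(x)) {
      abort(sprintf("%s file '%s' does not exist", what, x))
    }
  }
  check_path(network, "network")
  if (is.null(names(scores)) || any(names(scores) == "")) {
    abort("`scores` must be a named list")
  }
  for (nm in names(scores)) check_path(scores[[nm]], paste("score table", nm))
  for (nm in names(collections %||% list())) {
    check_path(collections[[nm]], paste("collection", nm))
  }
  for (nm in names(disease_genes %||% list())) {
    check_path(disease_genes[[nm]], paste("disease-gene list", nm))
  }
  for (nm in names(robustness_networks %||% list())) {
    check_path(robustness_networks[[nm]], paste("robustness network", nm))
  }
  if (is.character(background) && length(background) == 1L &&
      background != "network_lcc") {
    check_path(background, "background")
  }
  structure(list(network = network, scores = scores, null = null,
                 rule = rule, collections = collections,
                 background = background, disease_genes = disease_genes,
                 robustness_networks = robustness_networks,
                 out_dir = out_dir, seed = as.integer(seed),
                 dialect = dialect, max_threshold = max_threshold,
                 max_points = max_points),
            class = "pipeline_config")
}

load_network_input <- function(x, dialect = "generic", name = NULL) {
  if (inherits(x, "ppi_network")) return(x)
  suppressMessages(read_edge_list(x, dialect = dialect, name = name))
}

load_scores_input <- function(x, nm) {
  if (inherits(x, "gene_score_table")) {
    attr(x, "dataset") <- nm
    return(x)
  }
  suppressMessages(read_score_table(x, dataset_name = nm))
}

load_collection_input <- function(x) {
  if (is.character(x) && length(x) == 1L) read_gmt(x) else as_tibble(x)
}

load_gene_list_input <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_gene_list(x)
  } else {
    unique(normalize_ids(x))
  }
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on one network and several score tables:
#' per-dataset module detection (threshold sweep + selection), all pairwise
#' inter-module connectivity tests with edge-type composition, interactor
#' extraction, the union-component export, disease-gene overlap and
#' connectivity tests, and enrichment of the modules and of each directed
#' interactor set against the supplied collections. Results are written
#' under `config$out_dir` (`modules/`, `connectivity/`, `interactors/`,
#' `enrichment/`, `robustness/`, `manifest.json`, `summary.txt`); a stage
#' failure aborts the run but still writes a manifest recording the stages
#' completed. All tabular outputs are reproduced byte-identically by
#' re-running with the same config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the loaded inputs and all in-memory
#'   results (`modules`, `connectivity`, `interactors`, `enrichment`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  for (d in c("", "modules", "connectivity", "interactors", "enrichment",
              "robustness")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  stages <- list()
  results <- list()
  t_stage <- function(name, code) {
    t0 <- Sys.time()
    value <- force(code)
    stages[[name]] <<- list(
      status = "completed",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    value
  }
  summary_lines <- character(0)
  note <- function(...) summary_lines <<- c(summary_lines, sprintf(...))

  finish <- function(error = NULL) {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    digests <- as.list(tools::md5sum(files))
    names(digests) <- sub(paste0("^", out_dir, "/?"), "", names(digests))
    manifest <- list(
      package = "modlink",
      version = as.character(utils::packageVersion("modlink")),
      seed = config$seed,
      null = unclass(config$null), rule = unclass(config$rule),
      datasets = names(config$scores),
      stages = stages,
      error = if (is.null(error)) NULL else conditionMessage(error),
      outputs = digests)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }

  run_all <- function() {
    net <- t_stage("load_network", load_network_input(config$network,
                                                      config$dialect))
    results$network <<- net
    ns <- network_summary(net)
    readr::write_tsv(ns, file.path(out_dir, "network_stats.tsv"))
    note("network '%s': %d nodes, %d edges, LCC %d", net$name, ns$n_nodes,
         ns$n_edges, ns$lcc_size)

    tables <- t_stage("load_scores", purrr::imap(config$scores,
                                                 load_scores_input))
    tables <- purrr::map(tables,
                         function(tb) suppressMessages(restrict_to_network(tb, net)))

    fits <- t_stage("detect_modules", {
      purrr::imap(tables, function(tb, nm) {
        null_i <- config$null
        null_i$seed <- null_i$seed %||%
          derive_seed(config$seed, match(nm, names(tables)))
        suppressMessages(detect_module(net, tb, null = null_i,
                                       rule = config$rule,
                                       max_threshold = config$max_threshold,
                                       max_points = config$max_points))
      })
    })
    results$fits <<- fits
    modules <- list()
    for (nm in names(fits)) {
      fit <- fits[[nm]]
      write_sweep_trace(fit$sweep,
                        file.path(out_dir, "modules",
                                  paste0(nm, "_sweep.tsv")))
      if (is_module(fit$module)) {
        modules[[nm]] <- module_genes(fit$module)
        write_module(fit$module,
                     file.path(out_dir, "modules", paste0(nm, "_module.txt")),
                     file.path(out_dir, "modules",
                               paste0(nm, "_provenance.json")))
        note("module '%s': %d genes at threshold %.4g (z = %.3f)", nm,
             fit$module$lcc_size, fit$module$threshold, fit$module$z_score)
      } else {
        readr::write_tsv(fit$module$nearest_miss,
                         file.path(out_dir, "modules",
                                   paste0(nm, "_no_module.tsv")))
        note("module '%s': no qualifying component", nm)
      }
    }
    results$modules <<- modules

    if (length(modules) >= 2L) {
      conn <- t_stage("connectivity", {
        pairs <- utils::combn(names(modules), 2L, simplify = FALSE)
        purrr::map(pairs, function(pr) {
          null_i <- config$null
          null_i$seed <- null_i$seed %||%
            derive_seed(config$seed, 100L + match(pr[1L], names(modules)) * 10L +
                          match(pr[2L], names(modules)))
          ct <- inter_module_significance(net, modules[[pr[1L]]],
                                          modules[[pr[2L]]], null = null_i,
                                          labels = pr)
          comp <- if (ct$total >= 1L) {
            bind_rows(edge_type_composition_test(ct, net, pool_both = FALSE),
                      edge_type_composition_test(ct, net, pool_both = TRUE))
          } else {
            NULL
          }
          base <- file.path(out_dir, "connectivity",
                            paste0(pr[1L], "__", pr[2L]))
          readr::write_tsv(as_tibble(ct), paste0(base, ".tsv"))
          if (!is.null(comp)) {
            readr::write_tsv(comp, paste0(base, "_edge_types.tsv"))
          }
          note("connectivity %s - %s: %d cross edges (z = %.2f, p = %.3g)",
               pr[1L], pr[2L], ct$total, ct$z_score, ct$empirical_p)
          list(test = ct, composition = comp)
        })
      })
      results$connectivity <<- conn

      interactors <- t_stage("interactors", {
        it <- find_interactors(net, modules, include_unconnected = TRUE)
        readr::write_tsv(it, file.path(out_dir, "interactors",
                                       "interactors.tsv"))
        readr::write_tsv(interactor_summary(it),
                         file.path(out_dir, "interactors", "summary.tsv"))
        it
      })
      results$interactors <<- interactors
      linking <- filter(interactors, .data$target != "No module")
      note("%d interactor gene(s) across %d module pair(s)",
           dplyr::n_distinct(linking$gene),
           nrow(interactor_summary(interactors)))

      t_stage("union_component", {
        uc <- union_component(net, modules)
        export_subnetwork(net, uc$gene, annotations = uc,
                          path = file.path(out_dir, "connectivity",
                                           "union_component"))
        readr::write_tsv(uc, file.path(out_dir, "connectivity",
                                       "union_component_members.tsv"))
        results$union_component <<- uc
      })
    }

    bg <- if (identical(config$background, "network_lcc")) {
      component_members(largest_component(net))
    } else {
      load_gene_list_input(config$background)
    }
    results$background <<- bg

    if (!is.null(config$disease_genes)) {
      t_stage("disease_genes", {
        lists <- purrr::map(config$disease_genes, load_gene_list_input)
        overlaps <- purrr::imap(lists, function(dg, dn) {
          per_module <- purrr::imap(modules, function(mg, mn) {
            ov <- suppressMessages(hypergeom_overlap(mg, dg, bg))
            mutate(ov, module = mn, disease_list = dn,
                   overlap = purrr::map_chr(.data$overlap, paste,
                                            collapse = ","))
          })
          bind_rows(per_module)
        })
        overlaps <- bind_rows(overlaps)
        readr::write_tsv(overlaps, file.path(out_dir, "interactors",
                                             "disease_overlap.tsv"))
        results$disease_overlap <<- overlaps
        dconn <- purrr::imap(lists, function(dg, dn) {
          null_i <- config$null
          null_i$seed <- null_i$seed %||% derive_seed(config$seed, 900L)
          ct <- tryCatch(gene_set_connectivity(net, dg, null = null_i),
                         error = function(e) NULL)
          if (is.null(ct)) return(NULL)
          mutate(as_tibble(ct), disease_list = dn)
        })
        dconn <- bind_rows(dconn)
        if (nrow(dconn) > 0L) {
          readr::write_tsv(dconn, file.path(out_dir, "interactors",
                                            "disease_connectivity.tsv"))
          results$disease_connectivity <<- dconn
        }
      })
    }

    if (!is.null(config$collections) && length(modules) >= 1L) {
      t_stage("enrichment", {
        queries <- modules
        if (!is.null(results$interactors)) {
          linking <- filter(results$interactors, .data$target != "No module")
          dir_sets <- linking |>
            group_by(.data$home, .data$target) |>
            summarise(genes = list(unique(.data$gene)), .groups = "drop")
          for (i in seq_len(nrow(dir_sets))) {
            queries[[paste0(dir_sets$home[i], "_to_", dir_sets$target[i])]] <-
              dir_sets$genes[[i]]
          }
        }
        results$enrichment <<- purrr::imap(config$collections, function(coll, cn) {
          coll <- load_collection_input(coll)
          if (length(queries) >= 2L) {
            mat <- multi_set_enrichment_matrix(queries, coll, bg,
                                               min_queries = 0L)
            readr::write_tsv(mat, file.path(out_dir, "enrichment",
                                            paste0(cn, "_matrix.tsv")))
          }
          full <- purrr::imap(queries, function(q, qn) {
            r <- enrich_collection(q, coll, bg)
            mutate(as_tibble(r), query = qn, collection = cn,
                   overlap = purrr::map_chr(.data$overlap, paste,
                                            collapse = ","))
          })
          full <- bind_rows(full)
          readr::write_tsv(full, file.path(out_dir, "enrichment",
                                           paste0(cn, "_full.tsv")))
          note("enrichment vs '%s': %d significant set-query pairs", cn,
               sum(full$significant))
          full
        })
      })
    }

    if (!is.null(config$robustness_networks) && length(modules) >= 1L) {
      t_stage("robustness", {
        nets <- purrr::imap(config$robustness_networks, function(x, nm) {
          load_network_input(x, name = nm)
        })
        rob <- purrr::imap(modules, function(mg, mn) {
          null_i <- config$null
          null_i$seed <- null_i$seed %||% derive_seed(config$seed, 500L)
          r <- suppressMessages(cross_ppi_robustness(mg, nets, null = null_i,
                                                     z_min = config$rule$z_min))
          mutate(r, module = mn)
        })
        rob <- bind_rows(rob)
        write_robustness_report(rob, file.path(out_dir, "robustness",
                                               "robustness.tsv"))
        results$robustness <<- rob
      })
    }
    invisible(NULL)
  }

  err <- NULL
  tryCatch(run_all(), error = function(e) err <<- e)
  finish(err)
  if (!is.null(err)) stop(err)
  invisible(results)
}
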