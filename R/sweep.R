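#' Module selection rule
#'
#' The module is the induced LCC with a connectivity z-score above `z_min`
#' (default 1.6) and a size inside the band conventionally considered
#' reasonable for a disease module (30-100 genes); among qualifying rows
#' the highest z-score wins, with ties broken toward the smallest threshold
#' (smallest p-values). The sweep itself stops early once an induced LCC
#' exceeds `hard_cap` nodes, generalizing the manual practice of not
#' considering cutoffs once the component is already far too large.
#'
#' @param z_min Minimum z-score (default 1.6).
#' @param size_min,size_max Admissible module size band (defaults 30, 100).
#' @param hard_cap Sweep early-stop size (default 300).
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(z_min = 1.6, size_min = 30, size_max = 100,
                           hard_cap = 300) {
  if (!(size_min > 0 && size_min <= size_max && size_max < hard_cap)) {
    abort("need 0 < size_min <= size_max < hard_cap")
  }
  structure(list(z_min = z_min, size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 hard_cap = as.integer(hard_cap)),
            class = "selection_rule")
}

#' Data-driven p-value threshold grid
#'
#' Thresholds are placed at the observed distinct gene p-values up to
#' `max_threshold`, each bumped to the midpoint toward the next distinct
#' p-value so that, under the package-wide strict `p < t` rule, the cutoff
#' admits its own gene. The grid is thinned evenly (in rank space) to at
#' most `max_points` thresholds, so every admissible gene-set size range is
#' still covered.
#'
#' @param table A [gene_score_table()].
#' @param max_threshold Largest observed p-value to consider (default 0.05).
#' @param max_points Maximum number of grid points (default 60).
#' @return Increasing numeric vector of thresholds.
#' @export
make_threshold_grid <- function(table, max_threshold = 0.05, max_points = 60) {
  assert_scalar_number(max_threshold, "max_threshold", lower = 1e-300, upper = 1)
  assert_scalar_number(max_points, "max_points", lower = 1)
  p_all <- sort(unique(table$p_value))
  d <- p_all[p_all <= max_threshold]
  if (length(d) == 0L) abort("no p-values at or below `max_threshold`")
  nxt <- vapply(d, function(v) {
    above <- p_all[p_all > v]
    if (length(above) > 0L) above[1L] else min(1, v + (1 - v) / 2 + 1e-9)
  }, numeric(1))
  grid <- (d + nxt) / 2
  grid[nxt <= d] <- d[nxt <= d] + 1e-9  # degenerate guard (v == 1)
  if (length(grid) > max_points) {
    # even rank-space thinning; always keeps the largest admissible threshold
    keep <- sort(unique(round(seq(length(grid), 1L, length.out = max_points))))
    grid <- grid[keep]
  }
  grid
}

#' Threshold sweep of induced-LCC significance
#'
#' For each threshold `t` in the grid, takes the genes with `p < t` that are
#' present in the network, finds the largest connected component they induce,
#' and compares its size against random sets of the same gene count drawn
#' under the null model (degree-binned by default): `z = (lcc_size -
#' null_mean) / null_sd`. The null set size matches the count of
#' sub-threshold genes in the network, not the LCC size, mirroring the
#' observed selection process. Sweeping stops after the first row whose LCC
#' exceeds `rule$hard_cap`.
#'
#' @param net A [ppi_network()].
#' @param table A [gene_score_table()] (restricted to network genes
#'   internally).
#' @param grid Increasing thresholds; default [make_threshold_grid()].
#' @param null A [null_model_config()].
#' @param rule A [selection_rule()].
#' @return A `module_sweep`: tibble with one row per evaluated threshold
#'   (`threshold`, `n_genes_below`, `lcc_size`, `null_mean`, `null_sd`,
#'   `z_score`, `lcc_members` list-column) plus metadata attributes. Rows
#'   with degenerate nulls (`null_sd = 0`) carry `z_score = NA` and are
#'   ineligible for selection.
#' @export
run_sweep <- function(net, table, grid = NULL, null = null_model_config(),
                      rule = selection_rule()) {
  table <- suppressMessages(restrict_to_network(table, net))
  if (nrow(table) == 0L) abort("no scored genes present in the network")
  if (is.null(grid)) grid <- make_threshold_grid(table)
  if (length(grid) == 0L) abort("empty threshold grid")
  grid <- sort(grid)
  bins <- bins_for(net, null)
  csr <- net$csr
  rows <- vector("list", length(grid))
  with_seed_if(null$seed, {
    for (i in seq_along(grid)) {
      t <- grid[i]
      genes <- table$gene[table$p_value < t]
      idx0 <- match(genes, net$nodes) - 1L
      cv <- induced_component(net, idx0)
      counts <- target_bin_counts(bins, genes)
      null_sizes <- cpp_null_lcc(csr$indptr, csr$indices, csr$n_nodes,
                                 bins$bin_index0, as.integer(counts),
                                 null$n_samples)
      mu <- mean(null_sizes)
      sg <- sd(null_sizes)
      z <- if (is.na(sg) || sg == 0) NA_real_ else (cv$size - mu) / sg
      rows[[i]] <- tibble(threshold = t, n_genes_below = length(genes),
                          lcc_size = cv$size, null_mean = mu, null_sd = sg,
                          z_score = z, lcc_members = list(cv$members))
      if (cv$size > rule$hard_cap) break
    }
  })
  out <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (any(is.na(out$z_score))) {
    inform(sprintf("%d sweep row(s) with degenerate null (sd = 0); z undefined",
                   sum(is.na(out$z_score))))
  }
  structure(out, dataset = dataset_name(table), null = null, rule = rule,
            class = c("module_sweep", class(out)))
}

#' Select the module from a sweep
#'
#' Among sweep rows with a defined z-score above `rule$z_min` and an LCC
#' size within `[rule$size_min, rule$size_max]`, returns the highest-z row
#' as a `ppi_module`; ties go to the smallest threshold. When no row
#' qualifies, a structured `no_module_report` listing the nearest-miss rows
#' is returned instead (a valid outcome, not an error).
#'
#' @param sweep A [run_sweep()] result.
#' @param rule A [selection_rule()]; defaults to the rule stored on the
#'   sweep.
#' @return A `ppi_module` or a `no_module_report`.
#' @export
select_module <- function(sweep, rule = NULL) {
  if (nrow(sweep) == 0L) abort("empty sweep")
  rule <- rule %||% attr(sweep, "rule") %||% selection_rule()
  ok <- !is.na(sweep$z_score) & sweep$z_score > rule$z_min &
    sweep$lcc_size >= rule$size_min & sweep$lcc_size <= rule$size_max
  if (!any(ok)) {
    cand <- as_tibble(sweep) |>
      select(-"lcc_members") |>
      arrange(desc(.data$z_score)) |>
      head(5L)
    return(structure(list(dataset = attr(sweep, "dataset"), rule = rule,
                          nearest_miss = cand),
                     class = "no_module_report"))
  }
  hit <- sweep[ok, ]
  hit <- hit[order(-hit$z_score, hit$threshold), ][1L, ]
  structure(list(
    genes = sort(hit$lcc_members[[1L]]),
    threshold = hit$threshold,
    z_score = hit$z_score,
    lcc_size = hit$lcc_size,
    null_mean = hit$null_mean,
    null_sd = hit$null_sd,
    dataset = attr(sweep, "dataset"),
    null = attr(sweep, "null"),
    rule = rule),
    class = "ppi_module")
}

#' @export
print.ppi_module <- function(x, ...) {
  cat(sprintf("<ppi_module '%s'> %d genes at threshold %.4g (z = %.3f)\n",
              x$dataset, x$lcc_size, x$threshold, x$z_score))
  invisible(x)
}

#' @export
print.no_module_report <- function(x, ...) {
  cat(sprintf("<no_module_report '%s'> no sweep row satisfied z > %.2f and size in [%d, %d]\n",
              x$dataset %||% "scores", x$rule$z_min, x$rule$size_min,
              x$rule$size_max))
  cat("nearest-miss rows:\n")
  print(x$nearest_miss)
  invisible(x)
}

#' @rdname select_module
#' @param x Object returned by [select_module()] or [detect_module()].
#' @export
is_module <- function(x) {
  if (inherits(x, "module_fit")) x <- x$module
  inherits(x, "ppi_module")
}

#' @rdname select_module
#' @export
module_genes <- function(x) {
  if (inherits(x, "module_fit")) x <- x$module
  if (!inherits(x, "ppi_module")) return(character(0))
  x$genes
}

#' Detect an exposure/disease module
#'
#' End-to-end composition of [make_threshold_grid()], [run_sweep()] and
#' [select_module()]: rank genes by association p-value, score the induced
#' LCC at each data-driven threshold against the randomization null, and
#' pick the significant component of reasonable module size.
#'
#' @inheritParams run_sweep
#' @param max_threshold,max_points Grid construction, see
#'   [make_threshold_grid()].
#' @return A `module_fit` with elements `module` (a `ppi_module` or
#'   `no_module_report`) and `sweep` (the `module_sweep` trace). Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
detect_module <- function(net, table, null = null_model_config(),
                          rule = selection_rule(), max_threshold = 0.05,
                          max_points = 60) {
  table <- suppressMessages(restrict_to_network(table, net))
  grid <- make_threshold_grid(table, max_threshold, max_points)
  sweep <- run_sweep(net, table, grid, null, rule)
  module <- select_module(sweep, rule)
  structure(list(module = module, sweep = sweep,
                 dataset = dataset_name(table)),
            class = "module_fit")
}

#' @export
print.module_fit <- function(x, ...) {
  cat(sprintf("<module_fit '%s'> %d sweep rows\n", x$dataset, nrow(x$sweep)))
  print(x$module)
  invisible(x)
}

#' @rdname detect_module
#' @param x A `module_fit`.
#' @param ... Unused.
#' @export
tidy.module_fit <- function(x, ...) {
  as_tibble(x$sweep) |> select(-"lcc_members")
}

#' @rdname detect_module
#' @export
glance.module_fit <- function(x, ...) {
  m <- x$module
  if (is_module(m)) {
    tibble(dataset = x$dataset, selected = TRUE, threshold = m$threshold,
           module_size = m$lcc_size, z_score = m$z_score,
           null_mean = m$null_mean, null_sd = m$null_sd,
           n_thresholds = nrow(x$sweep))
  } else {
    tibble(dataset = x$dataset, selected = FALSE, threshold = NA_real_,
           module_size = NA_integer_, z_score = NA_real_,
           null_mean = NA_real_, null_sd = NA_real_,
           n_thresholds = nrow(x$sweep))
  }
}

#' Write sweep trace / module files
#'
#' The sweep trace is tab-separated (`threshold`, `n_genes_below`,
#' `lcc_size`, `null_mean`, `null_sd`, `z_score`); the module writer emits
#' a plain gene list plus a JSON provenance block (threshold, z, null
#' config, rule, dataset).
#'
#' @param sweep A `module_sweep`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_trace <- function(sweep, path) {
  readr::write_tsv(as_tibble(sweep) |> select(-"lcc_members"), path)
  invisible(path)
}

#' @rdname write_sweep_trace
#' @param module A `ppi_module`.
#' @param path_genes,path_provenance Gene-list and JSON output files.
#' @export
write_module <- function(module, path_genes, path_provenance = NULL) {
  writeLines(module$genes, path_genes)
  if (!is.null(path_provenance)) {
    prov <- list(dataset = module$dataset, threshold = module$threshold,
                 z_score = module$z_score, lcc_size = module$lcc_size,
                 null_mean = module$null_mean, null_sd = module$null_sd,
                 null = unclass(module$null), rule = unclass(module$rule))
    jsonlite::write_json(prov, path_provenance, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path_genes)
}
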