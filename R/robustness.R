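#' Cross-interactome robustness of a module
#'
#' Re-evaluates whether a module's genes still form a significantly
#' connected component in alternative interactomes: per network, the module
#' genes are mapped (only via an explicit identifier mapping, never by fuzzy
#' matching), their induced LCC size is computed, and that size is compared
#' against degree-matched random sets of the same mapped-gene count. A
#' module is flagged significant in a network when its z-score exceeds
#' `z_min` (the module-selection threshold is reused for coherence; this is
#' an assumption recorded in the output).
#'
#' @param module_genes Character vector of module genes.
#' @param networks Named list of [ppi_network()]s.
#' @param null A [null_model_config()].
#' @param mapping Optional named list of per-network identifier mappings
#'   (two-column data frames: source id, target id), applied before lookup.
#' @param z_min Significance threshold on the z-score (default 1.6).
#' @return Tibble with one row per network: `network`, `module_size`,
#'   `genes_found`, `lcc_size`, `null_mean`, `null_sd`, `z_score`,
#'   `significant` (`z > z_min`; `NA` when not assessable).
#' @export
cross_ppi_robustness <- function(module_genes, networks,
                                 null = null_model_config(),
                                 mapping = NULL, z_min = 1.6) {
  if (length(networks) == 0L) abort("need at least one network")
  if (is.null(names(networks))) {
    names(networks) <- vapply(networks, function(n) n$name, character(1))
  }
  module_genes <- unique(normalize_ids(module_genes))
  if (length(module_genes) == 0L) abort("`module_genes` must be nonempty")
  rows <- purrr::imap(networks, function(net, nm) {
    genes <- module_genes
    if (!is.null(mapping) && !is.null(mapping[[nm]])) {
      mp <- mapping[[nm]]
      map <- setNames(normalize_ids(mp[[2L]]), normalize_ids(mp[[1L]]))
      hit <- genes %in% names(map)
      genes[hit] <- map[genes[hit]]
      genes <- unique(genes)
    }
    mapped <- intersect(genes, net$nodes)
    found <- length(mapped)
    if (found == 0L) {
      inform(sprintf("network '%s': no module genes found; not assessable", nm))
      return(tibble(network = nm, module_size = length(module_genes),
                    genes_found = 0L, lcc_size = 0L, null_mean = NA_real_,
                    null_sd = NA_real_, z_score = NA_real_,
                    significant = NA))
    }
    if (found < length(module_genes)) {
      inform(sprintf("network '%s': %d of %d module genes found", nm, found,
                     length(module_genes)))
    }
    cv <- suppressMessages(induced_lcc(net, mapped))
    bins <- bins_for(net, null)
    counts <- as.integer(target_bin_counts(bins, mapped))
    csr <- net$csr
    null_sizes <- with_seed_if(null$seed,
      cpp_null_lcc(csr$indptr, csr$indices, csr$n_nodes, bins$bin_index0,
                   counts, null$n_samples))
    mu <- mean(null_sizes)
    sg <- sd(null_sizes)
    z <- if (is.na(sg) || sg == 0) NA_real_ else (cv$size - mu) / sg
    tibble(network = nm, module_size = length(module_genes),
           genes_found = found, lcc_size = cv$size, null_mean = mu,
           null_sd = sg, z_score = z,
           significant = if (is.na(z)) NA else z > z_min)
  })
  out <- bind_rows(rows)
  attr(out, "z_min") <- z_min
  out
}

#' @rdname cross_ppi_robustness
#' @param report A [cross_ppi_robustness()] table.
#' @param path Output file (tab-separated, Network / LCC / z-score layout).
#' @export
write_robustness_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
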