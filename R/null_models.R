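#' Null-model configuration
#'
#' Controls how "random expectation" is defined for every z-score and
#' empirical p-value in the package. The default, `degree_binned`, samples
#' random gene sets whose degree composition matches the observed set
#' (degree-preserving randomization via degree bins, the standard control
#' for hub bias in interactome analysis); `uniform` samples uniformly from
#' all network nodes (equivalently a single degree bin).
#'
#' @param method `"degree_binned"` or `"uniform"`.
#' @param n_samples Number of random sets per statistic (default 10,000).
#'   At least 100 are required for any reported p-value; reporting
#'   `p < 1e-5` requires at least 1e5 samples under the add-one convention.
#' @param min_bin_size Minimum nodes per degree bin (default 100).
#' @param seed Optional integer seed; when set, every consumer of this
#'   config produces identical draws across runs.
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(method = c("degree_binned", "uniform"),
                              n_samples = 10000, min_bin_size = 100,
                              seed = NULL) {
  method <- match.arg(method)
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  if (n_samples < 100) {
    warn("fewer than 100 null samples; empirical p-values will be coarse")
  }
  assert_scalar_number(min_bin_size, "min_bin_size", lower = 1)
  structure(list(method = method, n_samples = as.integer(n_samples),
                 min_bin_size = as.integer(min_bin_size),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "null_model_config")
}

#' Degree bins for degree-preserving sampling
#'
#' Partitions the network's nodes into bins of contiguous ascending degree
#' ranges by greedily merging consecutive degree classes until each bin
#' holds at least `min_bin_size` nodes; a final undersized bin is merged
#' into its predecessor. With `min_bin_size = 1` every distinct degree gets
#' its own bin (exact degree preservation).
#'
#' @param net A [ppi_network()].
#' @param min_bin_size Minimum nodes per bin.
#' @return A `degree_bins` object: per-bin node lists, degree ranges, and a
#'   node-to-bin index.
#' @export
build_degree_bins <- function(net, min_bin_size = 100) {
  assert_scalar_number(min_bin_size, "min_bin_size", lower = 1)
  if (length(net$nodes) == 0L) abort("network is empty")
  deg <- igraph::degree(net$graph)[net$nodes]
  if (length(net$nodes) < min_bin_size) {
    warn("network smaller than `min_bin_size`; using a single bin")
  }
  degs <- sort(unique(deg))
  bins <- list()
  cur <- integer(0)
  cur_lo <- NA_integer_
  for (d in degs) {
    if (length(cur) == 0L) cur_lo <- d
    cur <- c(cur, which(deg == d))
    if (length(cur) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- list(lo = cur_lo, hi = d, idx = cur)
      cur <- integer(0)
    }
  }
  if (length(cur) > 0L) {
    if (length(bins) == 0L) {
      bins[[1L]] <- list(lo = cur_lo, hi = max(degs), idx = cur)
    } else {
      last <- bins[[length(bins)]]
      bins[[length(bins)]] <- list(lo = last$lo, hi = max(degs),
                                   idx = c(last$idx, cur))
    }
  }
  node_bin <- integer(length(deg))
  for (b in seq_along(bins)) node_bin[bins[[b]]$idx] <- b
  structure(list(
    nodes = net$nodes,
    bin_nodes = lapply(bins, function(b) net$nodes[sort(b$idx)]),
    bin_index0 = lapply(bins, function(b) as.integer(sort(b$idx) - 1L)),
    node_bin = node_bin,
    degree_range = tibble(bin = seq_along(bins),
                          degree_min = vapply(bins, `[[`, numeric(1), "lo"),
                          degree_max = vapply(bins, `[[`, numeric(1), "hi"),
                          n_nodes = lengths(lapply(bins, `[[`, "idx"))),
    min_bin_size = as.integer(min_bin_size),
    network = net$name),
    class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  cat(sprintf("<degree_bins> %d bins over %d nodes (network '%s')\n",
              nrow(x$degree_range), length(x$nodes), x$network))
  print(x$degree_range)
  invisible(x)
}

# single-bin "uniform" pseudo-binning used when method = "uniform"
uniform_bins <- function(net) {
  structure(list(
    nodes = net$nodes,
    bin_nodes = list(net$nodes),
    bin_index0 = list(seq_along(net$nodes) - 1L),
    node_bin = rep(1L, length(net$nodes)),
    degree_range = tibble(bin = 1L, degree_min = NA_real_,
                          degree_max = NA_real_,
                          n_nodes = length(net$nodes)),
    min_bin_size = 1L, network = net$name),
    class = "degree_bins")
}

bins_for <- function(net, null) {
  if (null$method == "uniform") uniform_bins(net)
  else build_degree_bins(net, null$min_bin_size)
}

# per-bin counts of a target gene set (genes must be network nodes)
target_bin_counts <- function(bins, target) {
  idx <- match(target, bins$nodes)
  if (anyNA(idx)) abort("target genes must all be network nodes")
  tabulate(bins$node_bin[idx], nbins = length(bins$bin_nodes))
}

#' Sample a degree-matched gene set
#'
#' Draws `length(target)` nodes without replacement so that the number drawn
#' from each degree bin equals the target set's count in that bin. Feasible
#' by construction since target members belong to their own bins.
#'
#' @param bins A [build_degree_bins()] result.
#' @param target Character vector of gene identifiers (subset of the
#'   network's nodes).
#' @return Character vector of sampled genes, same length as `target`.
#' @export
sample_matched_set <- function(bins, target) {
  counts <- target_bin_counts(bins, unique(target))
  out <- character(0)
  for (b in seq_along(counts)) {
    if (counts[b] > 0L) {
      pool <- bins$bin_nodes[[b]]
      out <- c(out, pool[sample.int(length(pool), counts[b])])
    }
  }
  out
}

#' Add-one empirical p-value
#'
#' Returns `(r + 1) / (n + 1)` where `r` counts null values at least as
#' large as the observed statistic among `n` randomizations (greater tail).
#' The add-one convention never returns 0, so a claim of `p < 1e-5`
#' requires at least 1e5 randomizations.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics.
#' @param tail Only `"greater"` is defined.
#' @return A probability in `[1/(n+1), 1]`.
#' @export
empirical_p <- function(observed, null_values, tail = "greater") {
  tail <- match.arg(tail, "greater")
  if (length(null_values) == 0L) abort("`null_values` must be nonempty")
  (sum(null_values >= observed) + 1) / (length(null_values) + 1)
}

#' Write null-distribution diagnostics
#'
#' Audit file for any permutation analysis: method, sample count, seed,
#' null mean/sd, and the full null histogram as tab-separated counts.
#'
#' @param null_values Numeric vector of null statistics.
#' @param null A [null_model_config()].
#' @param path Output file.
#' @param label Analysis label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_null_diagnostics <- function(null_values, null, path, label = "null") {
  hdr <- sprintf("# %s\tmethod=%s\tn_samples=%d\tseed=%s\tmean=%.6g\tsd=%.6g",
                 label, null$method, length(null_values),
                 if (is.null(null$seed)) "NA" else null$seed,
                 mean(null_values), sd(null_values))
  tab <- as.data.frame(table(null_values), stringsAsFactors = FALSE)
  names(tab) <- c("value", "count")
  writeLines(hdr, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
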