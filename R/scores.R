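#' Gene-level association score tables
#'
#' A gene score table is a tibble with one row per gene and columns `gene`
#' (normalized identifier), `p_value` in \[0, 1\], and optionally
#' `effect_direction` (`"up"`, `"down"`, `"none"`) and `fold_change`.
#' `gene_score_table()` validates and normalizes a data frame into this
#' form; genes appearing on several rows keep their minimum p-value (the
#' collision is logged), mirroring site-to-gene aggregation.
#'
#' @param x Data frame with at least `gene` and `p_value` columns.
#' @param dataset_name Label carried in the `dataset` attribute.
#' @param case_fold Upper-case identifiers? See [normalize_ids()].
#' @return A tibble of class `gene_score_table`.
#' @export
gene_score_table <- function(x, dataset_name = "scores", case_fold = TRUE) {
  x <- as_tibble(x)
  if (!all(c("gene", "p_value") %in% names(x))) {
    abort("need `gene` and `p_value` columns")
  }
  if (anyNA(x$p_value) || any(x$p_value < 0 | x$p_value > 1)) {
    abort("p-values must be in [0, 1] with no missing values")
  }
  x$gene <- normalize_ids(x$gene, case_fold)
  n_in <- nrow(x)
  x <- x |>
    group_by(.data$gene) |>
    arrange(.data$p_value, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$p_value, .data$gene)
  if (nrow(x) < n_in) {
    inform(sprintf("%d duplicate gene row(s) collapsed to minimum p-value",
                   n_in - nrow(x)))
  }
  structure(x, dataset = dataset_name,
            class = c("gene_score_table", class(x)))
}

#' @rdname gene_score_table
#' @param table A `gene_score_table`.
#' @export
dataset_name <- function(table) attr(table, "dataset") %||% "scores"

#' Read / write score tables
#'
#' Tab-separated with a header; gene tables need `gene` and `p_value`
#' columns, site tables need `site` and `p_value` plus an optional `gene`
#' mapping column.
#'
#' @param path File path.
#' @param dataset_name Label for the table (defaults to the file name).
#' @param case_fold Upper-case identifiers?
#' @return A `gene_score_table` (or a site-score tibble for
#'   `read_site_scores()`).
#' @export
read_score_table <- function(path, dataset_name = NULL, case_fold = TRUE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  gene_score_table(x, dataset_name = dataset_name %||% basename(path),
                   case_fold = case_fold)
}

#' @rdname read_score_table
#' @export
read_site_scores <- function(path, case_fold = TRUE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("site", "p_value") %in% names(x))) {
    abort("need `site` and `p_value` columns")
  }
  if ("gene" %in% names(x)) x$gene <- normalize_ids(x$gene, case_fold)
  as_tibble(x)
}

#' @rdname read_score_table
#' @param table A score table.
#' @export
write_score_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

#' Aggregate site-level scores to genes
#'
#' Collapses CpG-site (or probe) p-values to one score per gene. Under the
#' `min_p` rule a gene's p-value is the minimum over its mapped sites, which
#' reproduces the membership rule "a gene is nominally significant when any
#' mapped site is" while also yielding a total ranking of genes. Sites with
#' no mapped gene are excluded (count logged).
#'
#' @param sites Tibble with columns `site`, `p_value`, and `gene` (may be
#'   `NA` for unmapped sites).
#' @param rule Aggregation rule; only `"min_p"` is defined.
#' @param dataset_name Label for the resulting table.
#' @return A [gene_score_table()].
#' @export
aggregate_sites_to_genes <- function(sites, rule = "min_p",
                                     dataset_name = "scores") {
  rule <- match.arg(rule, "min_p")
  sites <- as_tibble(sites)
  if (anyNA(sites$p_value) || any(sites$p_value < 0 | sites$p_value > 1)) {
    abort("site p-values must be in [0, 1]")
  }
  unmapped <- is.na(sites$gene) | sites$gene == ""
  if (any(unmapped)) {
    inform(sprintf("%d unmapped site(s) excluded", sum(unmapped)))
    sites <- sites[!unmapped, ]
  }
  if (nrow(sites) == 0L) abort("no mapped sites to aggregate")
  out <- sites |>
    group_by(.data$gene) |>
    summarise(p_value = min(.data$p_value), .groups = "drop")
  gene_score_table(out, dataset_name = dataset_name)
}

#' Nominally significant genes
#'
#' Genes with `p_value` strictly below `alpha` (boundary values are
#' excluded; thresholds act as strict cutoffs throughout the package).
#'
#' @param table A [gene_score_table()].
#' @param alpha Significance cutoff in (0, 1\]; default 0.05.
#' @return Character vector of gene identifiers.
#' @export
nominal_genes <- function(table, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", lower = 1e-300, upper = 1)
  table$gene[table$p_value < alpha]
}

#' Overlap summary of nominal gene sets
#'
#' Partitions the union of the tables' nominally significant gene sets into
#' Venn regions (every combination of membership) and reports each region's
#' count and members. Region counts sum to the size of the union.
#'
#' @param tables List of [gene_score_table()]s (named, or names taken from
#'   their `dataset` attributes).
#' @param alpha Nominal cutoff passed to [nominal_genes()].
#' @return Tibble with one row per nonempty-definable region: logical
#'   membership columns per table, `region` label, `n`, and a `genes`
#'   list-column.
#' @export
overlap_summary <- function(tables, alpha = 0.05) {
  if (length(tables) < 2L) abort("need at least two tables")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- vapply(tables, dataset_name, character(1))
  }
  sets <- lapply(tables, nominal_genes, alpha = alpha)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  rows <- purrr::pmap(combos, function(...) {
    inc <- c(...)
    label <- paste(names(sets)[inc], collapse = "&")
    genes <- universe[key == label]
    tibble(region = label, n = length(genes), genes = list(genes))
  })
  out <- bind_rows(purrr::map2(rows, seq_len(nrow(combos)), function(r, i) {
    bind_cols(as_tibble(combos[i, , drop = FALSE]), r)
  }))
  arrange(out, desc(.data$n))
}

#' Restrict a score table to network genes
#'
#' Keeps only genes present in the network (the "found in the PPI" step);
#' retained and dropped counts are logged. Genes in the network without a
#' score are unaffected elsewhere: the network keeps all its edges and
#' scoring stages simply never select unscored nodes.
#'
#' @param table A [gene_score_table()].
#' @param net A [ppi_network()].
#' @return The restricted `gene_score_table`.
#' @export
restrict_to_network <- function(table, net) {
  keep <- table$gene %in% net$nodes
  inform(sprintf("%d of %d gene(s) found in network '%s' (%d dropped)",
                 sum(keep), nrow(table), net$name, sum(!keep)))
  out <- table[keep, ]
  if (nrow(out) == 0L) warn("no scored genes found in the network")
  structure(out, dataset = dataset_name(table),
            class = c("gene_score_table", class(as_tibble(out))))
}
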