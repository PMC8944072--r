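#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Identifiers are normalized like network nodes; set names must be
#' unique.
#'
#' @param path GMT file.
#' @param case_fold Upper-case member identifiers?
#' @return Tibble with columns `set_name`, `description`, and a `genes`
#'   list-column.
#' @export
read_gmt <- function(path, case_fold = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  parts <- stringr::str_split(lines, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) abort(sprintf("GMT line %d has fewer than 3 fields", bad[1L]))
  out <- tibble(
    set_name = vapply(parts, `[[`, character(1), 1L),
    description = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) unique(normalize_ids(p[-(1:2)], case_fold))))
  if (anyDuplicated(out$set_name)) abort("GMT set names must be unique")
  out
}

#' @rdname read_gmt
#' @param collection A gene-set collection tibble.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set_name, description, genes, ...) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_gene_list <- function(path, case_fold = TRUE) {
  x <- readLines(path)
  x <- x[nzchar(stringr::str_trim(x)) & !startsWith(x, "#")]
  unique(normalize_ids(x, case_fold))
}

#' Hypergeometric overlap test
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of the observed overlap
#' between a query and a target gene set under a stated background: with
#' `N = |background|`, `K = |target|`, `n = |query|`, `k = |query & target|`.
#' Query or target members outside the background are dropped first, with
#' logged counts.
#'
#' @param query,target,background Character vectors of gene identifiers.
#' @return One-row tibble: `k`, `K`, `n`, `N`, `p_value`, and the
#'   overlapping genes as a list-column.
#' @export
hypergeom_overlap <- function(query, target, background) {
  background <- unique(normalize_ids(background))
  if (length(background) == 0L) abort("`background` must be nonempty")
  q0 <- unique(normalize_ids(query))
  t0 <- unique(normalize_ids(target))
  q <- intersect(q0, background)
  tg <- intersect(t0, background)
  dropped <- (length(q0) - length(q)) + (length(t0) - length(tg))
  if (dropped > 0L) {
    inform(sprintf("%d query/target gene(s) outside background dropped", dropped))
  }
  k <- length(intersect(q, tg))
  tibble(k = k, K = length(tg), n = length(q), N = length(background),
         p_value = phyper(k - 1, length(tg), length(background) - length(tg),
                          length(q), lower.tail = FALSE),
         overlap = list(sort(intersect(q, tg))))
}

#' Gene-set enrichment against a collection
#'
#' Hypergeometric enrichment of a query gene set against every set of a GMT
#' collection under an explicit background (e.g. the genes of the network's
#' largest connected component). Sets whose background-restricted size falls
#' outside `[min_set, max_set]` are not tested; Benjamini-Hochberg
#' adjustment is applied over the tested sets, and raw p-values are also
#' reported so any other correction can be re-applied.
#'
#' @param query Character vector of gene identifiers.
#' @param collection A [read_gmt()] collection.
#' @param background Character vector of background genes.
#' @param correction Only `"benjamini_hochberg"` is implemented.
#' @param min_set,max_set Background-restricted set-size band (defaults 3,
#'   1000).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return Tibble of class `enrichment_result`, sorted by raw p-value:
#'   `set_name`, `k` (overlap), `K` (set size in background), `n` (query
#'   size in background), `N` (background size), `p_value`, `adj_p_value`,
#'   `significant`, and an `overlap` list-column.
#' @export
enrich_collection <- function(query, collection, background,
                              correction = "benjamini_hochberg",
                              min_set = 3, max_set = 1000, alpha = 0.05) {
  correction <- match.arg(correction, "benjamini_hochberg")
  if (nrow(collection) == 0L) abort("`collection` is empty")
  if (min_set > max_set) abort("need min_set <= max_set")
  background <- unique(normalize_ids(background))
  q <- intersect(unique(normalize_ids(query)), background)
  if (length(q) == 0L) abort("no query genes in the background")
  rows <- purrr::pmap(collection, function(set_name, description, genes, ...) {
    tg <- intersect(genes, background)
    if (length(tg) < min_set || length(tg) > max_set) return(NULL)
    ov <- intersect(q, tg)
    tibble(set_name = set_name, k = length(ov), K = length(tg),
           n = length(q), N = length(background),
           p_value = phyper(length(ov) - 1, length(tg),
                            length(background) - length(tg), length(q),
                            lower.tail = FALSE),
           overlap = list(sort(ov)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(set_name = character(0), k = integer(0), K = integer(0),
                  n = integer(0), N = integer(0), p_value = numeric(0),
                  adj_p_value = numeric(0), significant = logical(0),
                  overlap = list())
  } else {
    out <- out |>
      mutate(adj_p_value = p.adjust(.data$p_value, method = "BH"),
             significant = .data$adj_p_value < alpha) |>
      arrange(.data$p_value, .data$set_name) |>
      select("set_name", "k", "K", "n", "N", "p_value", "adj_p_value",
             "significant", "overlap")
  }
  attr(out, "correction") <- correction
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Enrichment matrix over several query sets
#'
#' Runs [enrich_collection()] for each labelled query set and assembles a
#' pathway-by-query matrix of adjusted p-values, plus a count of query sets
#' in which each pathway is significant (the "significant in at least m
#' sets" view).
#'
#' @param queries Named list (>= 2) of gene sets.
#' @inheritParams enrich_collection
#' @param min_queries Keep only pathways significant in at least this many
#'   query sets (default 1; use 0 to keep all tested pathways).
#' @return Tibble: `set_name`, one adjusted-p column per query set, and
#'   `n_significant`.
#' @export
multi_set_enrichment_matrix <- function(queries, collection, background,
                                        min_set = 3, max_set = 1000,
                                        alpha = 0.05, min_queries = 1) {
  if (length(queries) < 2L || is.null(names(queries))) {
    abort("`queries` must be a named list of at least two gene sets")
  }
  res <- purrr::imap(queries, function(q, nm) {
    r <- enrich_collection(q, collection, background, min_set = min_set,
                           max_set = max_set, alpha = alpha)
    tibble(set_name = r$set_name, query = nm, adj_p_value = r$adj_p_value,
           significant = r$significant)
  })
  long <- bind_rows(res)
  if (nrow(long) == 0L) return(tibble(set_name = character(0),
                                      n_significant = integer(0)))
  wide <- long |>
    select("set_name", "query", "adj_p_value") |>
    tidyr::pivot_wider(names_from = "query", values_from = "adj_p_value")
  counts <- long |>
    group_by(.data$set_name) |>
    summarise(n_significant = sum(.data$significant), .groups = "drop")
  out <- left_join(wide, counts, by = "set_name") |>
    arrange(desc(.data$n_significant), .data$set_name)
  filter(out, .data$n_significant >= min_queries)
}
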