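# internal helpers shared across modules

EDGE_TYPES <- c("physical", "functional", "both")

#' Normalize gene identifiers
#'
#' Trims surrounding whitespace and, by default, upper-cases identifiers so
#' that symbol-case conventions from different sources agree. Case folding
#' can be disabled for identifier schemes where case is meaningful.
#'
#' @param x Character vector of identifiers.
#' @param case_fold Upper-case identifiers? Default `TRUE`.
#' @return Character vector of normalized identifiers.
#' @export
normalize_ids <- function(x, case_fold = TRUE) {
  x <- stringr::str_trim(as.character(x))
  if (case_fold) x <- toupper(x)
  x
}

# Collapse duplicate unordered pairs to one record each, resolving edge-type
# disagreement: any "both", or a physical/functional conflict, promotes to
# "both".
resolve_types <- function(types) {
  u <- unique(types)
  if (length(u) == 0L) return(NA_character_)  # empty-slice probe by dplyr
  if (length(u) == 1L) return(u)
  if ("both" %in% u || all(c("physical", "functional") %in% u)) return("both")
  u[[1L]]
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

# deterministic per-stage sub-seed, kept below .Machine$integer.max
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
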