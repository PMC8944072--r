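make_table <- function(genes, p) {
  quiet(gene_score_table(tibble::tibble(gene = genes, p_value = p), "toy"))
}

test_that("threshold grid admits every observed p-value via midpoint bumping", {
  tbl <- make_table(paste0("G", 1:4), c(0.001, 0.001, 0.03, 0.2))
  grid <- make_threshold_grid(tbl, max_threshold = 0.05)
  counts <- vapply(grid, function(t) sum(tbl$p_value < t), integer(1))
  expect_equal(counts, c(2L, 3L))

  g1 <- make_threshold_grid(tbl, max_threshold = 0.05, max_points = 1)
  expect_equal(vapply(g1, function(t) sum(tbl$p_value < t), integer(1)), 3L)

  expect_error(make_threshold_grid(tbl, max_threshold = 1e-6), "no p-values")
})

test_that("large grids are admissible and near-evenly thinned in rank space", {
  withr::with_seed(55, {
    tbl <- make_table(paste0("G", 1:2000), runif(2000))
  })
  grid <- make_threshold_grid(tbl, max_threshold = 1, max_points = 200)
  expect_lte(length(grid), 200L)
  p_sorted <- sort(unique(tbl$p_value))
  # every grid member admits at least one new gene (strict cutoff works)
  expect_true(all(vapply(grid, function(t) sum(tbl$p_value < t), integer(1)) > 0))
  # rank-space spacing within 2x of even spacing
  ranks <- vapply(grid, function(t) sum(p_sorted < t), integer(1))
  even <- length(p_sorted) / 200
  expect_true(all(diff(ranks) <= 2 * even))
  expect_true(all(diff(grid) > 0))
})

test_that("star-graph sweep row matches exhaustive enumeration of C(5,2) subsets", {
  star <- star_network()
  oracle <- oracle_exhaustive_lcc_null(star, 2)
  expect_equal(oracle$mean, 1.4)
  expect_equal(oracle$sd, sqrt(0.24), tolerance = 1e-12)
  exact_z <- (2 - oracle$mean) / oracle$sd
  expect_equal(exact_z, 1.224745, tolerance = 1e-6)

  tbl <- make_table(c("X", "Y1", "Y2", "Y3", "Y4"),
                    c(0.01, 0.02, 0.3, 0.4, 0.5))
  n_mc <- 20000
  sweep <- quiet(run_sweep(star, tbl, grid = 0.05,
                           null = null_model_config(method = "uniform",
                                                    n_samples = n_mc,
                                                    seed = 7)))
  expect_equal(sweep$n_genes_below, 2L)
  expect_equal(sweep$lcc_size, 2L)
  expect_setequal(sweep$lcc_members[[1L]], c("X", "Y1"))
  se_mean <- oracle$sd / sqrt(n_mc)
  expect_lt(abs(sweep$null_mean - oracle$mean), 3 * se_mean)
  se_sd <- oracle$sd / sqrt(2 * n_mc)
  expect_lt(abs(sweep$null_sd - oracle$sd), 3 * se_sd)
  expect_equal(sweep$z_score, exact_z, tolerance = 0.05)
})

test_that("degenerate nulls (sd = 0) yield undefined z, not infinity", {
  net <- t1_network()
  tbl <- make_table(c("A", "B", "C", "D", "E"), rep(0.01, 5))
  sweep <- quiet(run_sweep(net, tbl, grid = 0.05,
                           null = null_model_config(method = "uniform",
                                                    n_samples = 200,
                                                    seed = 3)))
  expect_equal(sweep$lcc_size, largest_component(net)$size)
  expect_equal(sweep$null_sd, 0)
  expect_true(is.na(sweep$z_score))
  # and such rows are ineligible for selection
  expect_false(is_module(select_module(sweep)))
})

test_that("LCC sizes are weakly increasing along the sweep", {
  net <- random_ppi(300, p = 0.02, seed = 12)
  withr::with_seed(6, {
    tbl <- quiet(gene_score_table(
      tibble::tibble(gene = network_nodes(net),
                     p_value = runif(length(network_nodes(net)))), "r"))
  })
  sweep <- quiet(run_sweep(net, tbl,
                           grid = make_threshold_grid(tbl, 0.5, 25),
                           null = null_model_config(n_samples = 100,
                                                    min_bin_size = 50,
                                                    seed = 2)))
  expect_true(all(diff(sweep$lcc_size) >= 0))
  expect_true(all(sweep$lcc_size <= sweep$n_genes_below))
  # permutation invariance: shuffled input rows give the identical sweep
  shuffled <- withr::with_seed(8, tbl[sample.int(nrow(tbl)), ])
  shuffled <- quiet(gene_score_table(shuffled, "r"))
  sweep2 <- quiet(run_sweep(net, shuffled,
                            grid = make_threshold_grid(tbl, 0.5, 25),
                            null = null_model_config(n_samples = 100,
                                                     min_bin_size = 50,
                                                     seed = 2)))
  expect_equal(tibble::as_tibble(sweep), tibble::as_tibble(sweep2))
})

test_that("Monte-Carlo null moments match exhaustive enumeration on small graphs", {
  withr::with_seed(99, {
    for (rep in 1:4) {
      n <- sample(8:12, 1)
      net <- random_ppi(n, p = 0.35, seed = 1000 + rep,
                        name = paste0("small", rep))
      n <- length(network_nodes(net))
      k <- sample(3:min(6, n - 1), 1)
      oracle <- oracle_exhaustive_lcc_null(net, k)
      tbl <- make_table(network_nodes(net),
                        c(rep(0.01, k), rep(0.9, n - k)))
      n_mc <- 20000
      sw <- quiet(run_sweep(net, tbl, grid = 0.05,
                            null = null_model_config(method = "uniform",
                                                     n_samples = n_mc,
                                                     seed = rep)))
      expect_lt(abs(sw$null_mean - oracle$mean),
                3 * oracle$sd / sqrt(n_mc) + 1e-12)
      expect_lt(abs(sw$null_sd - oracle$sd),
                3 * oracle$sd / sqrt(2 * n_mc) + 1e-12)
    }
  })
})

fake_sweep <- function(threshold, z, size) {
  structure(tibble::tibble(
    threshold = threshold, n_genes_below = size + 5L, lcc_size = size,
    null_mean = 1, null_sd = 1, z_score = z,
    lcc_members = lapply(size, function(s) sprintf("G%03d", seq_len(s)))),
    dataset = "fake", null = null_model_config(n_samples = 100, seed = 1),
    rule = selection_rule(),
    class = c("module_sweep", class(tibble::tibble())))
}

test_that("selection enforces the z > 1.6 and 30-100 size rule with highest-z choice", {
  sw <- fake_sweep(c(0.001, 0.010, 0.020), c(1.5, 2.0, 2.6),
                   c(40L, 55L, 150L))
  m <- select_module(sw)
  expect_true(is_module(m))
  expect_equal(m$threshold, 0.010)
  expect_equal(m$lcc_size, 55L)

  none <- select_module(fake_sweep(c(0.01, 0.02), c(1.2, 1.6), c(40L, 50L)))
  expect_s3_class(none, "no_module_report")
  expect_equal(nrow(none$nearest_miss), 2L)

  tie <- select_module(fake_sweep(c(0.01, 0.03), c(2.0, 2.0), c(40L, 60L)))
  expect_equal(tie$threshold, 0.01)  # smallest-threshold tie-break
})

test_that("selection agrees with an independent rule oracle on random sweeps", {
  oracle_select <- function(df, rule) {
    ok <- which(!is.na(df$z_score) & df$z_score > rule$z_min &
                  df$lcc_size >= rule$size_min & df$lcc_size <= rule$size_max)
    if (length(ok) == 0L) return(NA_real_)
    best <- ok[df$z_score[ok] == max(df$z_score[ok])]
    df$threshold[best[which.min(df$threshold[best])]]
  }
  rule <- selection_rule()
  withr::with_seed(404, {
    for (rep in 1:50) {
      nr <- sample(1:8, 1)
      sw <- fake_sweep(sort(runif(nr, 0.001, 0.1)),
                       round(runif(nr, 0, 4), 2),
                       as.integer(sample(c(5:150, 250, 350), nr)))
      want <- oracle_select(tibble::as_tibble(sw), rule)
      got <- select_module(sw, rule)
      if (is.na(want)) {
        expect_false(is_module(got))
      } else {
        expect_equal(got$threshold, want)
      }
    }
  })
})

test_that("detect_module recovers a planted module (seed-fixed regression)", {
  scn <- generate_study_scenario(scenario_config(seed = 1))
  fit <- quiet(detect_module(scn$network, scn$scores[[1L]],
                             null = null_model_config(seed = 11)))
  expect_true(is_module(fit))
  expect_gte(jaccard(module_genes(fit), scn$truth$modules[[1L]]), 0.5)
  # selected module invariants hold against network and score table
  m <- fit$module
  expect_true(all(m$genes %in% network_nodes(scn$network)))
  cv <- quiet(induced_lcc(scn$network, m$genes))
  expect_equal(cv$size, length(m$genes))  # connected induced subgraph
  tbl <- scn$scores[[1L]]
  expect_true(all(tbl$p_value[match(m$genes, tbl$gene)] < m$threshold))
  expect_gte(m$lcc_size, m$rule$size_min)
  expect_lte(m$lcc_size, m$rule$size_max)
  expect_gt(m$z_score, m$rule$z_min)
  g <- glance(fit)
  expect_true(g$selected)
  expect_equal(g$module_size, m$lcc_size)
  expect_equal(nrow(tidy(fit)), nrow(fit$sweep))
})

test_that("a single sub-threshold gene yields a no-module report", {
  net <- t1_network()
  tbl <- make_table(c("A", "B", "C", "D", "E"),
                    c(0.001, 0.9, 0.9, 0.9, 0.9))
  fit <- quiet(detect_module(net, tbl,
                             null = null_model_config(method = "uniform",
                                                      n_samples = 100,
                                                      seed = 1),
                             max_threshold = 0.5))
  expect_false(is_module(fit))
  expect_s3_class(fit$module, "no_module_report")
})

test_that("sweep traces and module files write and reload", {
  scn <- generate_study_scenario(scenario_config(seed = 1))
  fit <- quiet(detect_module(scn$network, scn$scores[[1L]],
                             null = null_model_config(n_samples = 200,
                                                      seed = 11)))
  dir <- withr::local_tempdir()
  write_sweep_trace(fit$sweep, file.path(dir, "sweep.tsv"))
  tr <- readr::read_tsv(file.path(dir, "sweep.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tr), nrow(fit$sweep))
  if (is_module(fit)) {
    write_module(fit$module, file.path(dir, "genes.txt"),
                 file.path(dir, "prov.json"))
    expect_equal(readLines(file.path(dir, "genes.txt")), fit$module$genes)
    prov <- jsonlite::read_json(file.path(dir, "prov.json"))
    expect_equal(prov$lcc_size, fit$module$lcc_size)
    expect_equal(prov$null$seed, 11L)
  }
})
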