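test_that("inter-module edge tallies match the toy network and are symmetric", {
  t1 <- t1_network()  # A-B physical, B-C functional, C-D both, D-E functional
  tally <- count_inter_module_edges(t1, c("A", "B"), c("C", "D"))
  expect_equal(tally$total, 1L)
  expect_equal(tally$functional, 1L)  # the B-C edge
  expect_equal(tally$physical + tally$both, 0L)

  disjoint <- quiet(ppi_network(data.frame(a = c("A", "F"), b = c("B", "G"))))
  expect_equal(count_inter_module_edges(disjoint, c("A", "B"),
                                        c("F", "G"))$total, 0L)

  expect_error(count_inter_module_edges(t1, c("A", "B"), c("B", "C"),
                                        shared = "error"), "share")
})

test_that("edge tallies equal an exhaustive edge-scan oracle", {
  net <- random_ppi(100, p = 0.05, seed = 17)
  withr::with_seed(19, {
    for (rep in 1:5) {
      a <- sample(network_nodes(net), 15)
      b <- sample(network_nodes(net), 20)  # may overlap a
      tally <- count_inter_module_edges(net, a, b)
      # oracle: scan every edge against the shared-exclusion rule
      a2 <- setdiff(a, b); b2 <- setdiff(b, a)
      edges <- network_edges(net)
      hit <- (edges$gene_a %in% a2 & edges$gene_b %in% b2) |
        (edges$gene_a %in% b2 & edges$gene_b %in% a2)
      expect_equal(tally$total, sum(hit))
      expect_equal(tally$functional, sum(hit & edges$type == "functional"))
      expect_equal(tally$total, tally$physical + tally$functional + tally$both)
      rev <- count_inter_module_edges(net, b, a)
      expect_equal(rev, tally)
    }
  })
})

test_that("adjacent cliques are maximally significant; add-one floor is exact", {
  # two planted cliques bridged by all pairs inside a sparse background
  base <- random_ppi(150, p = 0.01, seed = 23)
  a <- paste0("N", 1:5)
  b <- paste0("N", 6:10)
  extra <- rbind(t(utils::combn(a, 2)), t(utils::combn(b, 2)),
                 as.matrix(expand.grid(a, b, stringsAsFactors = FALSE)))
  all_edges <- rbind(as.matrix(network_edges(base)[, 1:2]), extra)
  net <- quiet(ppi_network(as.data.frame(all_edges)))
  res <- quiet(inter_module_significance(net, a, b,
                                         null = null_model_config(n_samples = 99,
                                                                  seed = 5)))
  expect_equal(res$total, 25L)
  expect_equal(res$empirical_p, 1 / 100)  # observed beats all 99 draws
  expect_gt(res$z_score, 3)
})

test_that("empirical p-values are calibrated for random degree-matched sets", {
  net <- random_ppi(400, p = 0.02, seed = 29)
  bins <- build_degree_bins(net, 100)
  n_rep <- 200
  ps <- withr::with_seed(31, vapply(seq_len(n_rep), function(r) {
    a <- sample_matched_set(bins, sample(network_nodes(net), 15))
    b <- setdiff(sample_matched_set(bins, sample(network_nodes(net), 20)), a)
    res <- inter_module_significance(net, a, b,
                                     null = null_model_config(n_samples = 199,
                                                              min_bin_size = 100))
    res$empirical_p
  }, numeric(1)))
  frac <- mean(ps <= 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("interactor extraction matches the toy case and a neighborhood oracle", {
  t1 <- t1_network()
  out <- find_interactors(t1, list(m1 = c("A", "B"), m2 = c("C", "D")))
  expect_setequal(out$gene, c("B", "C"))
  expect_equal(out$home[out$gene == "B"], "m1")
  expect_equal(out$target[out$gene == "B"], "m2")
  expect_equal(out$home[out$gene == "C"], "m2")

  none <- find_interactors(t1, list(m1 = "A", m2 = "E"))
  expect_equal(nrow(none), 0L)

  net <- random_ppi(120, p = 0.04, seed = 37)
  mods <- withr::with_seed(41, {
    nodes <- network_nodes(net)
    list(x = sample(nodes, 12), y = sample(nodes, 15), z = sample(nodes, 10))
  })
  out <- find_interactors(net, mods)
  edges <- network_edges(net)
  # oracle: per-gene neighborhood scan over every ordered pair
  for (home in names(mods)) {
    for (target in setdiff(names(mods), home)) {
      hset <- setdiff(mods[[home]], mods[[target]])
      tset <- setdiff(mods[[target]], mods[[home]])
      for (g in intersect(hset, network_nodes(net))) {
        nbrs <- c(edges$gene_b[edges$gene_a == g],
                  edges$gene_a[edges$gene_b == g])
        n_cross <- sum(nbrs %in% tset)
        row <- out[out$gene == g & out$home == home & out$target == target, ]
        if (n_cross == 0) {
          expect_equal(nrow(row), 0L)
        } else {
          expect_equal(row$n_edges, n_cross)
        }
      }
      # interactor consistency: summed cross edges == pair tally
      tall <- count_inter_module_edges(net, mods[[home]], mods[[target]])
      rows <- out[out$home == home & out$target == target, ]
      expect_equal(sum(rows$n_edges), tall$total)
    }
  }
})

test_that("include_unconnected adds 'No module' rows covering the remainder", {
  net <- random_ppi(80, p = 0.05, seed = 43)
  mods <- withr::with_seed(47, {
    nodes <- network_nodes(net)
    list(a = sample(nodes, 8), b = sample(nodes, 8))
  })
  full <- find_interactors(net, mods, include_unconnected = TRUE)
  for (nm in names(mods)) {
    # every network-mapped module member appears: as interactor or 'No module'
    listed <- unique(full$gene[full$home == nm])
    expect_setequal(listed, intersect(mods[[nm]], network_nodes(net)))
  }
  expect_true(all(full$n_edges[full$target == "No module"] == 0L))
  summ <- interactor_summary(full)
  expect_true(!"No module" %in% summ$target)
})

test_that("edge-type composition test matches exact enumeration", {
  # population of 10 edges, 4 functional; draw 3, observe 2 functional
  edges <- data.frame(
    a = paste0("A", 1:10), b = paste0("B", 1:10),
    type = c(rep("functional", 4), rep("physical", 6)))
  net <- quiet(ppi_network(edges))
  obs <- list(total = 3L, physical = 1L, functional = 2L, both = 0L)
  res <- edge_type_composition_test(obs, net)
  expect_equal(res$p_value, oracle_hypergeom_tail(10, 4, 3, 2))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  zero <- edge_type_composition_test(list(total = 3L, physical = 3L,
                                          functional = 0L, both = 0L), net)
  expect_equal(zero$p_value, 1)

  all_draw <- edge_type_composition_test(list(total = 10L, physical = 6L,
                                              functional = 4L, both = 0L), net)
  expect_equal(all_draw$p_value, 1)

  # pooling 'both' changes K and k and is recorded
  edges2 <- data.frame(a = paste0("A", 1:6), b = paste0("B", 1:6),
                       type = c("functional", "both", rep("physical", 4)))
  net2 <- quiet(ppi_network(edges2))
  r2 <- edge_type_composition_test(list(total = 2L, physical = 0L,
                                        functional = 1L, both = 1L), net2,
                                   pool_both = TRUE)
  expect_equal(r2$K_population, 2L)
  expect_equal(r2$k, 2L)
  expect_equal(r2$p_value, oracle_hypergeom_tail(6, 2, 2, 2))
})

test_that("gene-set connectivity scores a triangle positively and matches a pair scan", {
  base <- random_ppi(200, p = 0.008, seed = 53)
  tri <- c("T1", "T2", "T3")
  edges <- rbind(as.matrix(network_edges(base)[, 1:2]), t(utils::combn(tri, 2)))
  net <- quiet(ppi_network(as.data.frame(edges)))
  res <- gene_set_connectivity(net, tri,
                               null = null_model_config(n_samples = 200,
                                                        seed = 3))
  expect_equal(res$observed, 3L)
  expect_gt(res$z_score, 0)

  expect_error(gene_set_connectivity(net, "T1"), "fewer than 2")

  withr::with_seed(59, {
    for (rep in 1:5) {
      genes <- sample(network_nodes(net), 25)
      res <- gene_set_connectivity(net, genes,
                                   null = null_model_config(n_samples = 100,
                                                            seed = rep))
      pairs <- utils::combn(genes, 2)
      key <- paste(pmin(pairs[1, ], pairs[2, ]),
                   pmax(pairs[1, ], pairs[2, ]), sep = "\r")
      ekey <- paste(network_edges(net)$gene_a, network_edges(net)$gene_b,
                    sep = "\r")
      expect_equal(res$observed, sum(ekey %in% key))
    }
  })
  # LCC-size variant agrees with induced_lcc
  res_lcc <- gene_set_connectivity(net, tri, statistic = "lcc",
                                   null = null_model_config(n_samples = 100,
                                                            seed = 4))
  expect_equal(res_lcc$observed, quiet(induced_lcc(net, tri))$size)
})

test_that("mean z over random degree-matched sets is near zero", {
  net <- random_ppi(400, p = 0.02, seed = 61)
  bins <- build_degree_bins(net, 100)
  zs <- withr::with_seed(67, vapply(1:200, function(r) {
    genes <- sample_matched_set(bins, sample(network_nodes(net), 20))
    res <- gene_set_connectivity(net, genes,
                                 null = null_model_config(n_samples = 300))
    res$z_score
  }, numeric(1)))
  expect_lte(abs(mean(zs, na.rm = TRUE)), 0.15)
})

test_that("union_component spans bridged modules and reuses induced_lcc", {
  t1 <- t1_network()
  uc <- quiet(union_component(t1, list(m1 = c("A", "B"), m2 = c("C", "D"))))
  expect_setequal(uc$gene, c("A", "B", "C", "D"))
  expect_equal(attr(uc, "size"), 4L)

  two_comp <- quiet(ppi_network(data.frame(a = c("A", "B", "F"),
                                           b = c("B", "C", "G"))))
  uc2 <- quiet(union_component(two_comp, list(m1 = c("A", "B", "C"),
                                              m2 = c("F", "G"))))
  expect_setequal(uc2$gene, c("A", "B", "C"))

  net <- random_ppi(120, p = 0.04, seed = 71)
  mods <- withr::with_seed(73, {
    nodes <- network_nodes(net)
    list(x = sample(nodes, 10), y = sample(nodes, 10), z = sample(nodes, 10))
  })
  uc3 <- quiet(union_component(net, mods))
  ref <- quiet(induced_lcc(net, unique(unlist(mods))))
  expect_setequal(uc3$gene, component_members(ref))
  shared_label <- uc3$module[uc3$gene %in% intersect(mods$x, mods$y)]
  if (length(shared_label) > 0) expect_match(shared_label, "x.*y")
})
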