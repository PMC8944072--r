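test_that("edge-list loading collapses duplicates and drops self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tphysical", "B\tC\tfunctional", "B\tC\tfunctional"), f)
  net <- quiet(read_edge_list(f))
  expect_equal(length(network_nodes(net)), 3L)
  expect_equal(nrow(network_edges(net)), 2L)
  expect_equal(net$dropped$duplicates, 1L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tA\tphysical", f2)
  expect_message(net2 <- read_edge_list(f2), "self-loop")
  expect_equal(network_nodes(net2), "A")
  expect_equal(nrow(network_edges(net2)), 0L)
  expect_equal(net2$dropped$self_loops, 1L)
})

test_that("humannet dialect merges physical and functional link files", {
  fn <- withr::local_tempfile(fileext = ".tsv")
  ph <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "B\tC\t0.5"), fn)
  writeLines("A\tB\t0.7", ph)
  net <- quiet(read_edge_list(fn, dialect = "humannet", physical = ph))
  edges <- network_edges(net)
  expect_equal(edges$type[edges$gene_a == "A" & edges$gene_b == "B"], "both")
  expect_equal(edges$type[edges$gene_a == "B" & edges$gene_b == "C"],
               "functional")
})

test_that("unknown edge-type tokens are format errors naming the line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tphysical", "B\tC\tbanana"), f)
  expect_error(read_edge_list(f), "banana.*line 2")
  expect_error(read_edge_list(file.path(tempdir(), "no-such-file.tsv")),
               "cannot read")
})

test_that("conflicting duplicate types promote to 'both'", {
  net <- quiet(ppi_network(data.frame(a = c("A", "B"), b = c("B", "A"),
                                      type = c("physical", "functional"))))
  expect_equal(network_edges(net)$type, "both")
})

test_that("identifier normalization trims and case-folds (optionally)", {
  net <- quiet(ppi_network(data.frame(a = c(" tp53", "TP53"),
                                      b = c("EGFR ", "egfr"))))
  expect_equal(network_nodes(net), c("EGFR", "TP53"))
  expect_equal(nrow(network_edges(net)), 1L)
  net2 <- quiet(ppi_network(data.frame(a = "tp53", b = "TP53"),
                            case_fold = FALSE))
  expect_equal(sort(network_nodes(net2)), c("TP53", "tp53"))
})

test_that("largest_component matches the toy example and a BFS oracle", {
  path_plus_pair <- quiet(ppi_network(
    data.frame(a = c("A", "B", "C", "D", "F"), b = c("B", "C", "D", "E", "G"))))
  cv <- largest_component(path_plus_pair)
  expect_equal(cv$size, 5L)
  expect_equal(component_members(cv), c("A", "B", "C", "D", "E"))

  empty <- quiet(ppi_network(data.frame(a = character(0), b = character(0))))
  expect_equal(largest_component(empty)$size, 0L)

  net <- random_ppi(200, p = 0.012, seed = 7)
  expect_equal(largest_component(net)$size, oracle_lcc_size(net))
})

test_that("induced_lcc agrees with exhaustive component enumeration", {
  t1 <- t1_network()
  expect_equal(component_members(quiet(induced_lcc(t1, c("A", "B", "D")))),
               c("A", "B"))
  expect_equal(quiet(induced_lcc(t1, character(0)))$size, 0L)

  net <- random_ppi(150, p = 0.02, seed = 3)
  withr::with_seed(11, {
    for (rep in 1:5) {
      genes <- sample(network_nodes(net), 40)
      expect_equal(quiet(induced_lcc(net, genes))$size,
                   oracle_lcc_size(net, genes))
    }
  })
})

test_that("LCC size is invariant under node relabeling", {
  net <- random_ppi(80, p = 0.04, seed = 5)
  nodes <- network_nodes(net)
  perm <- withr::with_seed(2, setNames(sample(nodes), nodes))
  edges <- network_edges(net)
  relabeled <- quiet(ppi_network(data.frame(a = perm[edges$gene_a],
                                            b = perm[edges$gene_b],
                                            type = edges$type)))
  expect_equal(largest_component(relabeled)$size, largest_component(net)$size)
})

test_that("induced LCC size is monotone in the gene set and consistent at the top", {
  net <- random_ppi(120, p = 0.03, seed = 9)
  nodes <- network_nodes(net)
  withr::with_seed(4, {
    s <- sample(nodes, 30)
    t <- union(s, sample(nodes, 40))
  })
  expect_lte(quiet(induced_lcc(net, s))$size, quiet(induced_lcc(net, t))$size)
  expect_equal(quiet(induced_lcc(net, nodes))$size,
               largest_component(net)$size)
})

test_that("edge-list round-trip reproduces nodes, edges, and types exactly", {
  net <- random_ppi(60, p = 0.06, seed = 13)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- quiet(read_edge_list(f))
  expect_equal(network_nodes(back), network_nodes(net))
  expect_equal(network_edges(back), network_edges(net))
})

test_that("export_subnetwork round-trips and annotates", {
  t1 <- t1_network()
  base <- file.path(withr::local_tempdir(), "sub")
  out <- quiet(export_subnetwork(t1, c("A", "B", "C"), path = base))
  expect_true(file.exists(out$graphml))
  back <- quiet(read_edge_list(out$edge_list))
  expect_equal(network_edges(back),
               network_edges(t1)[network_edges(t1)$gene_a %in% c("A", "B"), ])
  g <- igraph::read_graph(out$graphml, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C"))

  ann <- data.frame(gene = c("A", "B"), module = c("m1", "m1"))
  expect_warning(
    out2 <- suppressMessages(export_subnetwork(t1, c("A", "B", "C"),
                                               annotations = ann,
                                               path = paste0(base, "2"))),
    "lack annotations")
  expect_equal(out2$nodes$module, c("m1", "m1", ""))
})

test_that("exported edge-type counts agree with cross- plus within-module tallies", {
  net <- random_ppi(100, p = 0.05, seed = 21)
  withr::with_seed(3, {
    a <- sample(network_nodes(net), 5)
    b <- sample(setdiff(network_nodes(net), a), 5)
  })
  base <- file.path(withr::local_tempdir(), "mods")
  out <- quiet(export_subnetwork(net, c(a, b), path = base))
  exported <- quiet(read_edge_list(out$edge_list))
  cross <- count_inter_module_edges(net, a, b)
  within_a <- network_edges(net)
  within_a <- sum(within_a$gene_a %in% a & within_a$gene_b %in% a)
  within_b <- network_edges(net)
  within_b <- sum(within_b$gene_a %in% b & within_b$gene_b %in% b)
  expect_equal(nrow(network_edges(exported)), cross$total + within_a + within_b)
})
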