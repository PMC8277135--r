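# causal-map encoding, harmonization, merging, adjacency export

test_that("read_concept_maps parses records and rejects malformed input", {
  f <- withr::local_tempfile(lines = c("E1,A,B,3", "E1,B,C", "E2,A,C,1"))
  maps <- read_concept_maps(f)
  expect_named(maps, c("E1", "E2"))
  expect_setequal(maps$E1$nodes, c("A", "B", "C"))
  expect_equal(nrow(maps$E1$links), 2)
  expect_equal(maps$E1$links$strength[maps$E1$links$source == "A"], 3L)
  expect_true(is.na(maps$E1$links$strength[maps$E1$links$source == "B"]))

  bad_loop <- withr::local_tempfile(lines = c("E1,A,B,1", "E1,A,A,2"))
  expect_error(read_concept_maps(bad_loop), "line 2.*self-loop", )
  bad_str <- withr::local_tempfile(lines = "E1,A,B,4")
  expect_error(read_concept_maps(bad_str), "strength '4' not an integer in 1-3")
  bad_str2 <- withr::local_tempfile(lines = "E1,A,B,two")
  expect_error(read_concept_maps(bad_str2), "not an integer in 1-3")
})

test_that("packaged fixture holds 11 maps with 8-24 nodes each", {
  maps <- read_concept_maps(fixture_path("expert_maps_synthetic.csv"))
  expect_length(maps, 11)
  sizes <- vapply(maps, function(m) length(m$nodes), integer(1))
  expect_true(all(sizes >= 8 & sizes <= 24))
})

test_that("harmonize collapses synonyms keeping the maximum strength", {
  m <- concept_map("E1", data.frame(
    source = c("worms", "polychaetes"), target = c("X", "X"),
    strength = c(2L, 3L)))
  syn <- synonym_table(c(worms = "mobile infauna",
                         polychaetes = "mobile infauna"))
  h <- harmonize(m, syn)
  expect_setequal(h$nodes, c("mobile infauna", "X"))
  expect_equal(nrow(h$links), 1)
  expect_equal(h$links$strength, 3L)

  # empty synonym table is the identity
  expect_equal(harmonize(m, NULL), m)

  # collapse onto a self-loop is dropped and reported
  m2 <- concept_map("E2", data.frame(source = "worms", target = "annelids"))
  syn2 <- synonym_table(c(worms = "mobile infauna", annelids = "mobile infauna"))
  expect_message(h2 <- harmonize(m2, syn2), "dropped 1 self-loop")
  expect_equal(nrow(h2$links), 0)
  expect_equal(nrow(attr(h2, "dropped_self_loops")), 1)
})

test_that("synonym tables must be closed after one application", {
  expect_error(synonym_table(c(a = "b", b = "c")), "not closed")
  expect_silent(synonym_table(c(a = "b", c = "b")))
})

test_that("harmonize is idempotent and never increases the node count", {
  for (s in 1:50) {
    cfg <- synthetic_config(seed = s, n_experts = 3, alias_rate = 0.6,
                            ensure_coverage = FALSE)
    gen <- generate_expert_maps(cfg)
    for (m in gen$maps) {
      h1 <- suppressMessages(harmonize(m, gen$synonyms))
      h2 <- suppressMessages(harmonize(h1, gen$synonyms))
      attr(h1, "dropped_self_loops") <- NULL
      attr(h2, "dropped_self_loops") <- NULL
      expect_identical(h1, h2)
      expect_lte(length(h1$nodes), length(m$nodes))
    }
  }
})

test_that("merge_concept_maps takes the nonredundant union with provenance", {
  m1 <- concept_map("E1", data.frame(source = "A", target = "B"))
  m2 <- concept_map("E2", data.frame(source = c("A", "B"), target = c("B", "C")))
  net <- merge_concept_maps(list(m1, m2))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$source == "A", ]
  expect_equal(ab$n_experts, 2L)

  # merging a map with itself keeps topology but doubles support counts
  twice <- merge_concept_maps(list(m2, m2))
  expect_equal(nrow(twice$nodes), 3)
  expect_equal(nrow(twice$edges), 2)
  expect_equal(twice$edges$n_experts, c(2L, 2L))

  expect_error(merge_concept_maps(list()), "empty")
})

test_that("merge is order-independent across seeded map collections", {
  for (s in 1:50) {
    gen <- generate_expert_maps(synthetic_config(
      seed = s, n_experts = 4, alias_rate = 0, ensure_coverage = FALSE))
    net1 <- merge_concept_maps(gen$maps)
    set.seed(s)
    net2 <- merge_concept_maps(gen$maps[sample(length(gen$maps))])
    expect_identical(net1$nodes, net2$nodes)
    expect_identical(net1$edges, net2$edges)
  }
})

test_that("merged size is bounded by the sum of the inputs", {
  gen <- generate_expert_maps(synthetic_config(seed = 3, alias_rate = 0))
  net <- merge_concept_maps(gen$maps)
  expect_lte(nrow(net$edges), sum(vapply(gen$maps, function(m) nrow(m$links), integer(1))))
  expect_lte(nrow(net$nodes), sum(vapply(gen$maps, function(m) length(m$nodes), integer(1))))
})

test_that("adjacency export honours the weight rule and round-trips", {
  m1 <- concept_map("E1", data.frame(source = c("A", "B"), target = c("B", "C"),
                                     strength = c(2L, NA)))
  m2 <- concept_map("E2", data.frame(source = "A", target = "B", strength = 3L))
  net <- merge_concept_maps(list(m1, m2))

  adj <- network_adjacency(net, "none")
  expect_equal(sum(adj), 2)
  expect_equal(adj["A", "B"], 1)

  expect_equal(network_adjacency(net, "max_strength")["A", "B"], 3)
  expect_equal(network_adjacency(net, "support_count")["A", "B"], 2)
  expect_error(network_adjacency(net, "banana"), "arg")

  # round trip preserves topology exactly
  back <- adjacency_to_network(network_adjacency(net, "support_count"),
                               "support_count")
  expect_identical(back$edges[, c("source", "target", "n_experts")],
                   net$edges[, c("source", "target", "n_experts")])

  f <- withr::local_tempfile()
  write_adjacency(network_adjacency(net, "support_count"), f)
  expect_equal(read_adjacency(f), network_adjacency(net, "support_count"))
})

test_that("summarize_network reports counts and the handshake identity", {
  single <- merge_concept_maps(list(
    concept_map("E1", data.frame(source = "A", target = "B"))))
  sm <- summarize_network(single)
  expect_equal(sm$n_nodes, 2)
  expect_equal(sm$n_edges, 1)

  gen <- generate_expert_maps(synthetic_config(seed = 5, alias_rate = 0))
  net <- merge_concept_maps(gen$maps)
  sm <- summarize_network(net)
  expect_equal(sum(sm$degrees$out_degree), sm$n_edges)
  expect_equal(sum(sm$degrees$in_degree), sm$n_edges)
})

test_that("GraphML and DOT exports carry edge attributes", {
  gen <- generate_expert_maps(synthetic_config(seed = 2, alias_rate = 0,
                                               n_experts = 3,
                                               ensure_coverage = FALSE))
  net <- merge_concept_maps(gen$maps)
  g <- withr::local_tempfile(fileext = ".graphml")
  d <- withr::local_tempfile(fileext = ".dot")
  write_network_graphml(net, g)
  write_network_dot(net, d)
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(net$edges))
  expect_true("support" %in% igraph::edge_attr_names(back))
  expect_gt(file.size(d), 0)
})
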