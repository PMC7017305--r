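test_that("interactome validation rejects loops, duplicates and bad scores", {
  ok <- interactome(data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                               score = c(1, -2)))
  expect_s3_class(ok, "interactome")
  expect_error(interactome(data.frame(node_a = "a", node_b = "a", score = 1)),
               "self-loop")
  expect_error(interactome(data.frame(node_a = c("a", "b"),
                                      node_b = c("b", "a"), score = 1:2)),
               "duplicate")
  expect_error(interactome(data.frame(node_a = "a", node_b = "b", score = NA)),
               "finite")
})

test_that("edge filtering keeps the ceil(f*m) largest |scores| with stable ties", {
  inter <- interactome(data.frame(node_a = paste0("a", 1:20),
                                  node_b = paste0("b", 1:20), score = 1:20))
  kept <- filter_interactome(inter, 0.15)
  expect_equal(sort(kept$score), c(18, 19, 20))

  expect_identical(filter_interactome(inter, 1), inter)

  ties <- interactome(data.frame(node_a = paste0("a", 1:10),
                                 node_b = paste0("b", 1:10), score = rep(2, 10)))
  kept_ties <- filter_interactome(ties, 0.25)
  expect_identical(kept_ties$node_a, paste0("a", 1:3))  # input order

  for (f in c(0.01, 0.1, 0.33, 0.5, 0.99)) {
    expect_equal(nrow(filter_interactome(inter, f)), ceiling(f * 20))
  }
  # absolute score, not signed
  signed <- interactome(data.frame(node_a = c("a", "c"), node_b = c("b", "d"),
                                   score = c(-5, 1)))
  expect_equal(filter_interactome(signed, 0.5)$score, -5)
  # value mode keeps everything at or above the nearest-rank threshold
  expect_equal(nrow(filter_interactome(ties, 0.25, mode = "value")), 10)
  expect_error(filter_interactome(inter, 0), "0, 1")
})

test_that("first-order networks contain seeds, neighbors and induced edges", {
  inter <- interactome(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                                  score = c(1, 1)))
  net <- build_first_order_network("A", inter)
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(igraph::ecount(net), 1)

  all_seeds <- build_first_order_network(c("A", "B", "C"), inter)
  expect_equal(igraph::ecount(all_seeds), 2)
  expect_setequal(igraph::V(all_seeds)$name, c("A", "B", "C"))

  dup <- data.frame(gene_id = c("A", "A"), log2_fc = c(1, 3))
  net_dup <- build_first_order_network(dup, inter)
  expect_equal(igraph::V(net_dup)$log2_fc[igraph::V(net_dup)$name == "A"], 2)

  withmiss <- build_first_order_network(c("A", "ZZ"), inter)
  expect_identical(igraph::graph_attr(withmiss, "missing_seeds"), "ZZ")
  expect_error(build_first_order_network("ZZ", inter), "no seed maps")

  # every non-seed node touches at least one seed (first-order property)
  study <- synthetic_study(n_genes = 120, n_planted = 12,
                           interactome_nodes = 120, seed = 23)
  net2 <- build_first_order_network(study$planted$genes, study$interactome)
  seeds <- igraph::V(net2)$name[igraph::V(net2)$seed]
  for (v in igraph::V(net2)$name[!igraph::V(net2)$seed]) {
    expect_gt(length(intersect(names(igraph::neighbors(net2, v)), seeds)), 0)
  }
})

test_that("betweenness matches the worked examples", {
  path3 <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  b <- node_betweenness(path3)
  expect_equal(b[["b"]], 1)
  expect_equal(b[["a"]], 0)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:5)
  expect_equal(unname(node_betweenness(star)), c(6, 0, 0, 0, 0))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("v", 1:4)
  expect_true(all(node_betweenness(k4) == 0))
})

test_that("betweenness agrees exactly with exhaustive path enumeration", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(3:7, 1)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- runif(1) < 0.45
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- paste0("v", seq_len(n))
    expect_equal(unname(node_betweenness(g)), betweenness_bruteforce(adj))
  }
})

test_that("topology classification reproduces the worked examples", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  rec <- classify_topology(star)
  expect_equal(rec$degree_cutoff[1], 4)  # mean 1.6 + 2 * pop SD 1.2
  expect_identical(rec$class[rec$node_id == "c"], "hub_bottleneck")
  expect_true(all(rec$class[rec$node_id != "c"] == "other"))

  path5 <- igraph::make_graph(c("a", "b", "b", "c", "c", "d", "d", "e"),
                              directed = FALSE)
  rec5 <- classify_topology(path5)
  expect_gt(rec5$degree_cutoff[1], 2)  # cutoff ~2.58 above the max degree
  expect_true(all(rec5$class == "other"))

  recb <- classify_topology(bridged_double_star())
  expect_setequal(recb$node_id[recb$class == "hub_bottleneck"], c("h1", "h2"))
  x <- recb[recb$node_id == "x", ]
  expect_equal(x$betweenness, 36)
  expect_identical(x$class, "nonhub_bottleneck")
})

test_that("classification invariants hold on random first-order networks", {
  set.seed(31)
  for (rep in 1:10) {
    inter <- simulate_interactome(80, 2, seed = rep)
    seeds <- sample(unique(c(inter$node_a, inter$node_b)), 8)
    net <- build_first_order_network(seeds, inter)
    rec <- classify_topology(net)
    expect_false(any(duplicated(rec$node_id)))
    hubs <- rec$node_id[rec$class == "hub_bottleneck"]
    expect_true(all(rec$degree[rec$class == "hub_bottleneck"] >=
                      rec$degree_cutoff[1]))
    for (v in rec$node_id[rec$class == "nonhub_bottleneck"]) {
      expect_lt(rec$degree[rec$node_id == v], rec$degree_cutoff[1])
      expect_gt(rec$betweenness[rec$node_id == v], 0)
      expect_gte(length(intersect(names(igraph::neighbors(net, v)), hubs)), 2)
    }
  }
})

test_that("sample-SD switch raises the cutoff", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  pop <- classify_topology(star)$degree_cutoff[1]
  smp <- classify_topology(star, sd_sample = TRUE)$degree_cutoff[1]
  expect_gt(smp, pop)
})

test_that("cross-condition comparison flags shared nodes and opposite trends", {
  rec_a <- data.frame(node_id = c("h1", "h2", "n1"),
                      class = c("hub_bottleneck", "hub_bottleneck",
                                "nonhub_bottleneck"),
                      log2_fc = c(1, 2, 1))
  rec_b <- data.frame(node_id = c("h1", "h3"),
                      class = c("hub_bottleneck", "hub_bottleneck"),
                      log2_fc = c(-1, 2))
  cmp <- compare_clusters(rec_a, rec_b)
  hubs <- cmp$hub_bottleneck
  shared <- hubs[hubs$in_a & hubs$in_b, ]
  expect_identical(shared$node_id, "h1")
  expect_false(shared$concordant)  # +1 vs -1: opposite expression trend
  expect_setequal(hubs$node_id[hubs$in_a & !hubs$in_b], "h2")
  expect_setequal(hubs$node_id[!hubs$in_a & hubs$in_b], "h3")

  same <- compare_clusters(rec_a, rec_a)
  expect_true(all(same$hub_bottleneck$in_a & same$hub_bottleneck$in_b))
  expect_true(all(same$hub_bottleneck$concordant))
})
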