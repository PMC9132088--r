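# annotated network assembly, merging, and exports

mk_results <- function() {
  data.frame(
    protein_id = c("P1", "P2", "P3", "P4", "P5"),
    aapl_score = c(3, 0.5, 2, -1, -2),
    epo_fc = c(4, 2, 3, 1, 1),
    level = c("L1", "L2", "L1", "none", "none"),
    string_type = c("T1", "T2", "T3", "T4", "T4"),
    n_sites = 1:5, stringsAsFactors = FALSE)
}

mk_edges <- function() {
  data.frame(
    protein_a = c("BAIT", "BAIT", "P1", "P2", "P4", "P5"),
    protein_b = c("P1", "P2", "P3", "P4", "P5", "P9"),
    combined_score = c(0.95, 0.55, 0.8, 0.45, 0.6, 0.9),
    stringsAsFactors = FALSE)
}

test_that("network includes bait, interactors, and connected grey nodes", {
  g <- build_network(mk_results(), mk_edges(), "BAIT")
  nodes <- igraph::V(g)$name
  # P4 is grey but connected to the L2 interactor P2; P5 is grey and only
  # touches P4 (grey) and P9 (not classified) -> excluded; P9 never enters
  expect_setequal(nodes, c("BAIT", "P1", "P2", "P3", "P4"))
  v <- igraph::as_data_frame(g, what = "vertices")
  expect_true(v$is_bait[v$name == "BAIT"])
  expect_equal(v$level[v$name == "P2"], "L2")
  expect_equal(sum(v$is_bait), 1L)

  e <- igraph::as_data_frame(g, what = "edges")
  bait_p1 <- e[(e$from == "BAIT" & e$to == "P1") |
               (e$to == "BAIT" & e$from == "P1"), ]
  expect_equal(bait_p1$style, "solid")        # bait-T1 edge
  expect_equal(bait_p1$opacity_band, "high")  # score 0.95 >= 0.9
  p1_p3 <- e[(e$from == "P1" & e$to == "P3") |
             (e$to == "P1" & e$from == "P3"), ]
  expect_equal(p1_p3$style, "dashed")         # involves a T3 protein
  expect_equal(p1_p3$opacity_band, "mid")     # 0.8 in [0.7, 0.9)
  p2_p4 <- e[(e$from == "P2" & e$to == "P4") |
             (e$to == "P2" & e$from == "P4"), ]
  expect_equal(p2_p4$style, "backslash")      # involves a T4 protein
  expect_equal(p2_p4$opacity_band, "low")     # 0.45 in [0.4, 0.7)
  # every edge endpoint is a node and has a source edge in the input
  expect_true(all(c(e$from, e$to) %in% nodes))

  # a graph with no edges is still a valid node-only graph
  g0 <- build_network(mk_results(), mk_edges()[0, ], "BAIT")
  expect_equal(igraph::ecount(g0), 0)
  expect_setequal(igraph::V(g0)$name, c("BAIT", "P1", "P2", "P3"))
})

test_that("merging obeys inclusion-exclusion and keeps max edge scores", {
  res_a <- mk_results(); edges_a <- mk_edges()
  res_b <- data.frame(protein_id = c("P3", "Q1", "P1"),
                      aapl_score = c(2, 5, 4), epo_fc = c(9, 9, 9),
                      level = c("L1", "L1", "L1"),
                      string_type = c("T1", "T2", "T2"),
                      n_sites = c(1L, 2L, 3L), stringsAsFactors = FALSE)
  edges_b <- data.frame(protein_a = c("BAIT2", "BAIT2", "P1"),
                        protein_b = c("P3", "Q1", "P3"),
                        combined_score = c(0.9, 0.8, 0.99),
                        stringsAsFactors = FALSE)
  ga <- build_network(res_a, edges_a, "BAIT")
  gb <- build_network(res_b, edges_b, "BAIT2")
  gm <- merge_networks(ga, gb)
  va <- igraph::V(ga)$name; vb <- igraph::V(gb)$name
  expect_equal(igraph::vcount(gm),
               length(va) + length(vb) - length(intersect(va, vb)))
  v <- igraph::as_data_frame(gm, what = "vertices")
  expect_setequal(v$name[v$shared], intersect(va, vb))
  # shared node carries both attribute sets
  p3 <- v[v$name == "P3", ]
  expect_equal(p3$level_a, "L1"); expect_equal(p3$level_b, "L1")
  expect_equal(p3$epo_fc_a, 3);   expect_equal(p3$epo_fc_b, 9)
  # duplicate edge P1-P3 keeps the max combined score (0.99 from B)
  e <- igraph::as_data_frame(gm, what = "edges")
  dup <- e[(e$from == "P1" & e$to == "P3") |
           (e$from == "P3" & e$to == "P1"), ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$combined_score, 0.99)

  # disjoint graphs: simple union with zero shared
  gb2 <- build_network(res_b[res_b$protein_id == "Q1", , drop = FALSE],
                       edges_b[2, , drop = FALSE], "BAIT2")
  gm2 <- merge_networks(ga, gb2)
  expect_equal(sum(igraph::V(gm2)$shared), 0)
  # identical graphs: shared count equals node count
  gm3 <- merge_networks(ga, ga)
  expect_equal(sum(igraph::V(gm3)$shared), igraph::vcount(ga))
})

test_that("inclusion-exclusion holds on random graph pairs", {
  withr::local_seed(404)
  for (i in 1:10) {
    ids <- paste0("R", 1:20)
    pick <- function() {
      n <- sample(3:10, 1)
      data.frame(protein_id = sample(ids, n),
                 aapl_score = runif(n, -1, 3), epo_fc = runif(n, 0, 5),
                 level = sample(c("L1", "L2", "none"), n, replace = TRUE),
                 string_type = sample(paste0("T", 1:4), n, replace = TRUE),
                 n_sites = sample(0:9, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    ra <- pick(); rb <- pick()
    ea <- data.frame(protein_a = "A_BAIT", protein_b = ra$protein_id,
                     combined_score = runif(nrow(ra), 0.4, 1))
    eb <- data.frame(protein_a = "B_BAIT", protein_b = rb$protein_id,
                     combined_score = runif(nrow(rb), 0.4, 1))
    ga <- build_network(ra, ea, "A_BAIT")
    gb <- build_network(rb, eb, "B_BAIT")
    gm <- merge_networks(ga, gb)
    va <- igraph::V(ga)$name; vb <- igraph::V(gb)$name
    expect_equal(igraph::vcount(gm),
                 length(union(va, vb)))
    expect_equal(sum(igraph::V(gm)$shared), length(intersect(va, vb)))
  }
})

test_that("GraphML round-trip preserves node and edge attributes", {
  g <- build_network(mk_results(), mk_edges(), "BAIT")
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, path)
  g2 <- read_network_graphml(path)
  v1 <- igraph::as_data_frame(g, what = "vertices")
  v2 <- igraph::as_data_frame(g2, what = "vertices")
  v2 <- v2[match(v1$name, v2$name), names(v1)]
  rownames(v1) <- rownames(v2) <- NULL
  v2$is_bait <- as.logical(v2$is_bait)
  expect_equal(v2, v1)
  e1 <- igraph::as_data_frame(g, what = "edges")
  e2 <- igraph::as_data_frame(g2, what = "edges")
  key <- function(e) order(pmin(e$from, e$to), pmax(e$from, e$to))
  e1 <- e1[key(e1), ]; e2 <- e2[key(e2), names(e1)]
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e2, e1)
  # SIF export writes the three files
  paths <- write_network_sif(g, file.path(withr::local_tempdir(), "net"))
  expect_true(all(file.exists(paths)))
})
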