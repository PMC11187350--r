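test_that("gene sets map onto the graph by exact symbol membership", {
  g <- ppi_from_edges(c("A", "B"), c("B", "C"))
  m <- map_gene_set(g, gene_set("s", c("A", "B", "Z")))
  expect_equal(m$mapped, c("A", "B"))
  expect_equal(m$dropped, "Z")
  expect_equal(map_gene_set(g, c("q", "r"))$mapped, character(0))
  full <- map_gene_set(g, c("a", "b", "c"))  # case-normalized
  expect_equal(full$dropped, character(0))
  expect_setequal(c(m$mapped, m$dropped), c("A", "B", "Z"))
})

test_that("multi-source distances equal elementwise-min per-source BFS", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  expect_equal(single_source_distances(g, "A"),
               c(A = 0L, B = 1L, C = 2L, D = 3L, E = 4L))
  # two sources: min over independent BFS runs (oracle)
  got <- single_source_distances(g, c("A", "E"))
  adj <- oracle_adjacency(ppi_nodes(g), ppi_edges(g)$from, ppi_edges(g)$to)
  want <- pmin(oracle_bfs(adj, "A"), oracle_bfs(adj, "E"))
  expect_equal(got[names(want)], as.integer(want), ignore_attr = TRUE)

  # disconnected component absent from the map
  g2 <- ppi_from_edges(c("A", "X"), c("B", "Y"))
  d2 <- single_source_distances(g2, "A")
  expect_setequal(names(d2), c("A", "B"))
  expect_error(single_source_distances(g, character(0)), "non-empty")
  expect_error(single_source_distances(g, "ZZ"), "not in graph")
})

test_that("closest and internal distances follow the formulas", {
  g5 <- path_graph(c("A", "B", "C", "D", "E"))
  expect_equal(closest_distance_directed(path_graph(c("A", "B", "C")),
                                         "A", "C")$value, 2)
  # Y = {D, E}: D is 2 from B, E is 3 from B -> mean 2.5
  cd <- closest_distance_directed(g5, c("A", "B"), c("D", "E"))
  expect_equal(cd$value, 2.5)
  expect_equal(cd$n_excluded, 0L)

  # disjoint components -> undefined with all of Y excluded
  g2 <- ppi_from_edges(c("A", "X"), c("B", "Y"))
  cd2 <- closest_distance_directed(g2, c("A", "B"), c("X", "Y"))
  expect_true(is.na(cd2$value))
  expect_equal(cd2$n_excluded, 2L)

  # value 0 iff every reachable member of Y is inside X
  expect_equal(closest_distance_directed(g5, c("A", "B"), c("A", "B"))$value, 0)
  expect_gt(closest_distance_directed(g5, c("A", "B"), c("A", "C"))$value, 0)

  # internal distance: ends of a path are 2 apart via nearest-other
  expect_equal(internal_distance(path_graph(c("A", "B", "C")),
                                 c("A", "C")), 2)
  singleton <- internal_distance(g5, "A")
  expect_equal(as.numeric(singleton), 0)
  expect_true(attr(singleton, "singleton"))
  expect_true(is.na(internal_distance(g2, c("A", "X"))))
})

test_that("separation matches the hand-worked path-graph example", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  res <- separation(g, gene_set("herb", c("A", "B"), "herb_target"),
                    gene_set("sym", c("D", "E")))
  expect_equal(res$d_ab, 2.5)
  expect_equal(res$d_aa, 1)
  expect_equal(res$d_bb, 1)
  expect_equal(res$s_ab, 1.5)
  expect_equal(res$status, "ok")
  expect_equal(res$s_ab, res$d_ab - (res$d_aa + res$d_bb) / 2,
               tolerance = 1e-9)

  # self-comparison: d_ab = 0, s_ab = -d_aa < 0
  self <- separation(g, c("B", "D"), c("B", "D"))
  expect_equal(self$d_ab, 0)
  expect_equal(self$s_ab, -self$d_aa)
  expect_lt(self$s_ab, 0)

  # unmapped symptom set -> undefined, no error
  und <- separation(g, c("A", "B"), c("Q", "R"))
  expect_equal(und$status, "undefined")
  expect_true(is.na(und$s_ab))
  expect_equal(und$n_mapped_b, 0L)
})

test_that("symmetrized separation is symmetric; directed form is not forced to be", {
  set.seed(42)
  for (i in 1:20) {
    el <- random_edgelist(20, 0.12)
    g <- ppi_from_edges(el$from, el$to)
    nodes <- ppi_nodes(g)
    A <- sample(nodes, 4)
    B <- sample(setdiff(nodes, A), 5)
    ab <- separation(g, A, B)
    ba <- separation(g, B, A)
    if (ab$status == "ok") {
      expect_equal(ab$s_ab, ba$s_ab, tolerance = 1e-12)
      expect_equal(ab$d_ab, ba$d_ab, tolerance = 1e-12)
    } else {
      expect_equal(ba$status, "undefined")
    }
  }
})

test_that("separation agrees with the exhaustive BFS oracle on random graphs", {
  set.seed(202)
  n_checked <- 0
  for (rep in 1:50) {
    n <- sample(8:50, 1)
    el <- random_edgelist(n, runif(1, 0.05, 0.25))
    if (length(el$from) == 0) next
    g <- ppi_from_edges(el$from, el$to)
    D <- oracle_all_pairs(el$nodes, el$from, el$to)
    nodes <- ppi_nodes(g)
    if (length(nodes) < 10) next
    for (draw in 1:4) {
      A <- sample(nodes, sample(2:5, 1))
      B <- sample(setdiff(nodes, A), sample(2:5, 1))
      got <- separation(g, A, B)
      want <- oracle_separation(D, A, B)
      dir_want <- oracle_closest(D, A, B)
      dir_got <- separation(g, A, B, directed = TRUE)
      if (is.na(want$s_ab)) {
        expect_equal(got$status, "undefined")
      } else {
        expect_equal(got$d_ab, want$d_ab, tolerance = 1e-9)
        expect_equal(got$d_aa, want$d_aa, tolerance = 1e-9)
        expect_equal(got$d_bb, want$d_bb, tolerance = 1e-9)
        expect_equal(got$s_ab, want$s_ab, tolerance = 1e-9)
      }
      if (!is.na(dir_want) && dir_got$status == "ok") {
        expect_equal(dir_got$d_ab, dir_want, tolerance = 1e-9)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 150)
})

test_that("adding edges never increases pairwise distances", {
  set.seed(7)
  el <- random_edgelist(15, 0.15)
  g1 <- ppi_from_edges(el$from, el$to)
  # add 10 extra random edges on the same node set
  extra <- random_edgelist(15, 0.1)
  g2 <- ppi_from_edges(c(el$from, extra$from), c(el$to, extra$to))
  for (s in ppi_nodes(g1)[1:3]) {
    d1 <- single_source_distances(g1, s)
    d2 <- single_source_distances(g2, s)
    common <- intersect(names(d1), names(d2))
    expect_true(all(d2[common] <= d1[common]))
    expect_true(all(names(d1) %in% names(d2)))
  }
})

test_that("overlap genes intersect the herb set with the symptom union", {
  herb <- gene_set("h", c("APC", "CTNNB1", "EGF"), "herb_target")
  sets <- list(gene_set("s1", c("STAT3", "APC")),
               gene_set("s2", c("CTNNB1", "CASP8")))
  expect_equal(overlap_genes(herb, sets), c("APC", "CTNNB1"))
  expect_equal(overlap_genes(herb, list(gene_set("s", "ZZZ3"))),
               character(0))
  expect_equal(overlap_genes(gene_set("h", c("B", "A"), "herb_target"),
                             list(gene_set("s", c("A", "B", "C")))),
               c("A", "B"))
  expect_error(overlap_genes(herb, list()), "non-empty")
})

test_that("batch separation preserves order and renders undefined rows", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  herb <- gene_set("herb", c("A", "B"), "herb_target")
  syms <- list(gene_set("near", c("B", "C")),
               gene_set("unmapped", c("Q", "R")),
               gene_set("far", c("D", "E")))
  res <- batch_separation(g, herb, syms)
  tab <- separation_table(res)
  expect_equal(tab$symptom, c("near", "unmapped", "far"))
  expect_equal(tab$status, c("ok", "undefined", "ok"))

  # undefined entries appear as "-" in the written report
  man <- write_results(list(separation = tab), tempfile())
  lines <- readLines(man$path)
  expect_match(lines[3], "\t-\t-\t-\t-\t.*undefined")
})
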