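test_that("graph construction follows the >= t edge rule", {
  pw <- make_pw(c("A", "B", "C", "D"),
                list(c("A", "B", 0.5), c("B", "C", 0.4), c("C", "D", 0.1)))
  g <- build_graph(pw, threshold = 0.4)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2L)
  expect_setequal(apply(el, 1, paste, collapse = "-"), c("A-B", "B-C"))
  # ties at exactly t are included (B-C has weight exactly 0.4)
  expect_true("C" %in% igraph::V(g)$name)

  # above the maximum weight: empty graph
  empty <- build_graph(pw, threshold = 0.6)
  expect_equal(igraph::vcount(empty), 0L)
  expect_equal(igraph::ecount(empty), 0L)

  # t = -Inf: complete graph on all SNPs
  full <- build_graph(pw, threshold = -Inf)
  expect_equal(igraph::vcount(full), 4L)
  expect_equal(igraph::ecount(full), choose(4, 2))

  # vertex weights travel from the main-effect table
  mains <- structure(c(A = 0.01, B = 0.02, C = 0.03, D = 0.04), base = 2,
                     class = "main_effect_table")
  gm <- build_graph(pw, mains, 0.4)
  expect_equal(igraph::V(gm)$mutual_information[match("B", igraph::V(gm)$name)],
               0.02)
})

test_that("significance filtering keeps p <= alpha edges and prunes isolates", {
  pw <- make_pw(c("A", "B", "C", "D"),
                list(c("A", "B", 0.5), c("B", "C", 0.4), c("C", "D", 0.3)))
  pw$p_value <- ifelse(pw$ig > 0, c(0.001, 0.5, 0.009)[match(pw$ig, c(0.5, 0.4, 0.3))], 1)
  g <- build_graph(pw, threshold = 0.3)
  f <- filter_significant(g, alpha = 0.01)
  expect_setequal(igraph::V(f)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(f), 2L)  # B-C (p = 0.5) dropped
  expect_identical(igraph::as_edgelist(filter_significant(f, 0.01)),
                   igraph::as_edgelist(f))  # idempotent
  # alpha = 1 keeps everything
  expect_equal(igraph::ecount(filter_significant(g, 1)), 3L)
  # all edges p = 1 at alpha 0.01: empty graph
  pw2 <- pw; pw2$p_value <- rep(1, nrow(pw))
  expect_equal(igraph::vcount(filter_significant(build_graph(pw2, threshold = 0.3), 0.01)), 0L)
  # missing p-values refused
  pw3 <- pw; pw3$p_value <- NULL
  expect_error(filter_significant(build_graph(pw3, threshold = 0.3), 0.01),
               "p_value", class = "episnet_validation_error")
})

test_that("the threshold sweep nests and matches independent per-threshold builds", {
  grid <- threshold_grid(0.02, 0, 0.001)
  expect_length(grid, 21L)
  expect_equal(grid[1], 0.02)
  expect_equal(grid[21], 0)

  set.seed(41)
  ids <- sprintf("S%02d", 1:12)
  pw <- make_pw(ids)
  pw$ig <- round(runif(nrow(pw), -0.002, 0.022), 5)
  attr(pw, "snp_ids") <- ids
  sw <- threshold_sweep(pw, 0.02, 0, 0.001)
  expect_s3_class(sw, "threshold_sweep")
  # nesting: counts never decrease as t decreases
  expect_true(all(diff(sw$n_edges) >= 0))
  expect_true(all(diff(sw$n_vertices) >= 0))
  # oracle equivalence against independent build_graph at every grid point
  for (k in seq_along(grid)) {
    g <- build_graph(pw, threshold = grid[k])
    expect_equal(sw$n_edges[k], igraph::ecount(g))
    expect_equal(sw$n_vertices[k], igraph::vcount(g))
    comp <- attr(sw, "components")[[k]]
    expect_equal(sum(comp), igraph::vcount(g))  # sizes partition the vertices
    if (igraph::vcount(g) > 0)
      expect_equal(comp[1], max(igraph::components(g)$csize))
  }

  # a single edge enters exactly when the grid first reaches its weight
  one <- make_pw(c("A", "B", "C"), list(c("A", "B", 0.0137)))
  swo <- threshold_sweep(one, 0.02, 0, 0.001)
  expect_equal(swo$n_edges, as.integer(swo$threshold <= 0.0137))
})

test_that("connected components come back in deterministic descending order", {
  pw <- make_pw(c("A", "B", "C", "D", "E", "F", "G"),
                list(c("A", "B", 1), c("C", "D", 1)))
  comps <- graph_components(build_graph(pw, threshold = 0.5))
  expect_equal(lengths(comps), c(2L, 2L))
  expect_equal(comps[[1]], c("A", "B"))  # lexicographic tie-break

  path3 <- make_pw(c("A", "B", "C"), list(c("A", "B", 1), c("B", "C", 1)))
  expect_equal(graph_components(build_graph(path3, threshold = 0.5)),
               list(c("A", "B", "C")))

  star <- make_pw(c("H", paste0("L", 1:5)),
                  lapply(1:5, function(k) c("H", paste0("L", k), 1)))
  expect_equal(lengths(graph_components(build_graph(star, threshold = 0.5))), 6L)
  expect_length(graph_components(igraph::make_empty_graph(0, directed = FALSE)), 0L)
})

test_that("degree distributions satisfy their structural identities", {
  star <- make_pw(c("H", "X", "Y", "Z"),
                  list(c("H", "X", 1), c("H", "Y", 1), c("H", "Z", 1)))
  dd <- degree_dist(build_graph(star, threshold = 0.5))
  expect_equal(dd$degree, c(1L, 3L))
  expect_equal(dd$p, c(0.75, 0.25))

  # handshake lemma on random graphs
  for (s in 1:5) {
    set.seed(s)
    ids <- sprintf("S%02d", 1:10)
    pw <- make_pw(ids)
    pw$ig <- runif(nrow(pw))
    g <- build_graph(pw, threshold = 0.7)
    if (igraph::vcount(g) == 0) next
    dd <- degree_dist(g)
    expect_equal(sum(dd$degree * dd$count), 2 * igraph::ecount(g))
    expect_equal(dd$n_vertices, igraph::vcount(g))
    expect_true(all(dd$degree >= 1L))
  }

  expect_error(degree_dist_from_counts(c(0, 1), c(2, 3)), ">= 1",
               class = "episnet_validation_error")
})

test_that("the published degree column reconstructs integer counts and 255 edges", {
  p <- table1_p()
  counts <- p * 319
  # fractions are printed to 3 significant figures, so scaled counts sit
  # within 0.2 of integers (e.g. 0.201 * 319 = 64.12)
  expect_true(all(abs(counts - round(counts)) < 0.2))
  dd <- degree_dist_from_counts(seq_along(p), round(counts))
  expect_equal(dd$n_vertices, 319L)
  expect_equal(sum(dd$degree * dd$count), 510)
  expect_equal(edges_from_degrees(dd), 255)
})

test_that("graph exports round-trip and DOT encodes the visual scalings", {
  pw <- make_pw(c("A", "B", "C"), list(c("A", "B", 0.5), c("B", "C", 0.4)))
  pw$p_value <- c(0.001, 0.002, 1)[match(pw$ig, c(0.5, 0.4, -1))]
  mains <- structure(c(A = 0.01, B = 0.02, C = 0.005), base = 2,
                     class = "main_effect_table")
  g <- build_graph(pw, mains, 0.4)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- read_graphml(gml)
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::E(back)$information_gain),
               sort(igraph::E(g)$information_gain))
  expect_equal(sort(igraph::V(back)$mutual_information),
               sort(igraph::V(g)$mutual_information))

  et <- withr::local_tempfile(fileext = ".tsv")
  vt <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(g, et)
  write_vertex_table(g, vt)
  ed <- read.table(et, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(sort(ed$information_gain), c(0.4, 0.5))
  expect_true(all(c("snp_a", "snp_b", "information_gain", "p_value") %in% names(ed)))
  vd <- read.table(vt, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(sort(vd$snp_id), c("A", "B", "C"))

  dot <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, dot)
  txt <- readLines(dot)
  expect_true(any(grepl("vertex width = mutual_information", txt)))
  expect_true(any(grepl("penwidth = information_gain", txt)))
  expect_true(any(grepl("graph", txt)))
})
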