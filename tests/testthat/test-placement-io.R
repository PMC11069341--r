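# jplace ingestion, taxonomy consensus, query assignment, grouping.

test_that("a minimal jplace file parses and validates", {
  jp <- read_jplace(minimal_jplace())
  expect_s3_class(jp$tree, "phylo")
  expect_setequal(jp$tree$tip.label, c("A", "B", "C", "D"))
  expect_equal(nrow(jp$placements), 1L)
  expect_equal(jp$placements$name, "query1")
  expect_equal(jp$placements$like_weight_ratio, 1.0)
  expect_equal(length(jp$edge_node), 7L) # 6 internal-facing edges + root tag
  # edge 0 sits above tip A
  expect_equal(unname(jp$edge_node[["0"]]),
               which(jp$tree$tip.label == "A"))
})

test_that("structurally broken jplace files are rejected by key name", {
  path <- file.path(tempdir(), "broken.jplace")
  writeLines('{"version": 3, "tree": "(A:1{0},B:1{1}):0{2};",
              "placements": []}', path)
  expect_error(read_jplace(path), "fields")
  writeLines('{"version": 3,
              "placements": [], "fields": ["edge_num","like_weight_ratio"]}',
              path)
  expect_error(read_jplace(path), "tree")
})

test_that("jplace write/read round trip is stable", {
  jp <- read_jplace(minimal_jplace())
  out <- file.path(tempdir(), "rt.jplace")
  write_jplace(jp, out)
  jp2 <- read_jplace(out)
  expect_equal(jp2$placements, jp$placements)
  expect_equal(jp2$edge_node, jp$edge_node)
  expect_equal(ape::write.tree(jp2$tree), ape::write.tree(jp$tree))
  # idempotence on a larger simulated set
  sc <- simulate_placements(simulate_tree(12, seed = 3),
                            data.frame(node = 14, label = "cA", u = 1),
                            seed = 8)
  write_jplace(sc$jplace, out)
  rt <- read_jplace(out)
  expect_equal(rt$placements$name, sc$jplace$placements$name)
  expect_equal(rt$placements$like_weight_ratio,
               sc$jplace$placements$like_weight_ratio, tolerance = 1e-12)
  write_jplace(rt, out)
  expect_equal(read_jplace(out)$placements, rt$placements)
})

test_that("consensus taxonomy is the longest common prefix", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tax <- c(a = "Bacteria;Proteo;Alpha", b = "Bacteria;Proteo;Gamma",
           c = "Archaea;Thermo;X", d = "Archaea;Thermo;X")
  cons <- consensus_taxonomy(tree, tax)
  n_tip <- 4
  parent_ab <- ape::getMRCA(tree, c("a", "b"))
  parent_cd <- ape::getMRCA(tree, c("c", "d"))
  expect_equal(cons[parent_ab], "Bacteria;Proteo")
  expect_equal(cons[parent_cd], "Archaea;Thermo;X") # identical paths kept fully
  expect_equal(cons[ape::getMRCA(tree, c("a", "c"))], "") # disjoint domains
  expect_error(consensus_taxonomy(tree, c(tax[-1], a = "")), "malformed")
})

make_two_cluster_jplace <- function() {
  # ((A,B),(C,D)) with clusters I = {A,B} (u=1), II = {C,D} (u=0)
  path <- file.path(tempdir(), "two.jplace")
  writeLines(paste0(
    '{"version": 3,',
    ' "tree": "((A:0.1{0},B:0.2{1}):0.3{2},(C:0.1{3},D:0.1{4}):0.2{5}):0{6};",',
    ' "placements": [',
    '  {"p": [[0, -10, 0.6], [3, -11, 0.4]], "n": ["q_split"]},',
    '  {"p": [[1, -10, 1.0]], "n": ["q_in_I"]},',
    '  {"p": [[3, -10, 0.5], [4, -11, 0.5]], "n": ["q_in_II"]}],',
    ' "fields": ["edge_num", "likelihood", "like_weight_ratio"]}'
  ), path)
  jp <- read_jplace(path)
  lca_ab <- ape::getMRCA(jp$tree, c("A", "B"))
  lca_cd <- ape::getMRCA(jp$tree, c("C", "D"))
  at <- annotated_tree(jp$tree,
                       data.frame(node = c(lca_ab, lca_cd),
                                  label = c("I", "II"), u = c(1, 0)),
                       leaf_metadata = data.frame(
                         leaf_id = c("A", "B", "C", "D"),
                         taxonomy = c("Bac;P;A", "Bac;P;B", "Bac;Q;C",
                                      "Bac;Q;D")))
  list(jp = jp, at = at)
}

test_that("queries are assigned to the cluster with most LWR mass (best hit)", {
  f <- make_two_cluster_jplace()
  asg <- assign_queries(f$jp, f$at)
  asg <- asg[order(asg$query), ]
  split_row <- asg[asg$query == "q_split", ]
  expect_equal(split_row$cluster, "I")
  expect_equal(split_row$confidence, 0.6)
  expect_equal(split_row$status, "functional")
  in1 <- asg[asg$query == "q_in_I", ]
  expect_equal(in1$cluster, "I")
  expect_equal(in1$confidence, 1.0)
  expect_equal(in1$taxonomy, "Bac;P;B") # best edge above leaf B
  in2 <- asg[asg$query == "q_in_II", ]
  expect_equal(in2$cluster, "II")
  expect_equal(in2$status, "non_functional")
  expect_equal(in2$taxonomy, "Bac;Q;C") # tie broken to lower edge number
})

test_that("assignment is invariant to a common scaling of a query's LWRs", {
  f <- make_two_cluster_jplace()
  jp2 <- f$jp
  jp2$placements$like_weight_ratio <- jp2$placements$like_weight_ratio * 0.5
  a1 <- assign_queries(f$jp, f$at)
  a2 <- assign_queries(jp2, f$at)
  expect_equal(a1$cluster, a2$cluster)
  expect_equal(a1$best_edge, a2$best_edge)
  expect_equal(a1$taxonomy, a2$taxonomy)
})

test_that("low-quality placements are filtered with a faithful report", {
  asg <- data.frame(query = c("q1", "q2"), cluster = "I", u = 1,
                    status = "functional", taxonomy = NA,
                    confidence = c(0.9, 0.3), best_edge = 0L)
  flt <- filter_low_quality(asg, 0.5)
  expect_equal(nrow(flt$kept), 1L)
  expect_equal(flt$summary$n_discarded, 1L)
  expect_equal(flt$summary$pct_discarded, 50)
  expect_equal(flt$summary$mean_confidence_kept, 0.9)
  expect_equal(nrow(filter_low_quality(asg, 0)$discarded), 0L)
})

test_that("discard fraction tracks the confidence distribution's CDF", {
  set.seed(17)
  n <- 4000
  conf <- runif(n) # known CDF: F(q) = q
  asg <- data.frame(query = sprintf("q%04d", seq_len(n)), cluster = "I",
                    u = 1, status = "functional", taxonomy = NA,
                    confidence = conf, best_edge = 0L)
  for (thr in c(0.2, 0.5, 0.8)) {
    frac <- filter_low_quality(asg, thr)$summary$pct_discarded / 100
    se <- sqrt(thr * (1 - thr) / n)
    expect_lt(abs(frac - thr), 3 * se)
  }
})

test_that("groups aggregate TPM and unique-query richness per context", {
  asg <- data.frame(query = c("q1", "q2", "q3"), cluster = "I", u = 1,
                    status = "functional", taxonomy = "Bac;P;x",
                    confidence = 1, best_edge = 0L)
  ab <- data.frame(query_id = c("q1", "q2", "q3"),
                   context = "epi", tpm = c(5, 5, 10))
  g <- build_groups(asg, ab, rank = 2)
  expect_equal(nrow(g), 1L)
  expect_equal(g$abundance_tpm, 20)
  expect_equal(g$d_obs, 3L)
  expect_equal(g$taxon, "Bac;P")

  # two contexts: independent groups, total TPM conserved
  ab2 <- rbind(ab, data.frame(query_id = c("q1", "q2"),
                              context = "meso", tpm = c(1, 2)))
  g2 <- build_groups(asg, ab2, rank = 2)
  expect_equal(nrow(g2), 2L)
  expect_equal(sum(g2$abundance_tpm), sum(ab2$tpm))

  expect_error(build_groups(asg, rbind(ab, ab[1, ]), rank = 2), "duplicated")
  expect_warning(
    build_groups(asg, rbind(ab, data.frame(query_id = "ghost",
                                           context = "epi", tpm = 1)),
                 rank = 2),
    "never placed")
  expect_error(build_groups(asg, ab[1:2, ], rank = 2), "missing from")
})
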