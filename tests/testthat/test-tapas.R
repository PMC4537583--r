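# expression matrix with a query isoform, an exact foreign copy, a
# correlated sibling isoform (same gene), and an anti-correlated stranger
cluster_fixture <- function() {
  expr <- rbind(Q.1 = c(1, 5, 9, 5, 1),
                Q.2 = c(1.1, 5.2, 9.1, 5.1, 1.2),   # sibling isoform, same gene
                C.1 = c(1, 5, 9, 5, 1),             # exact copy, other gene
                D.1 = c(9, 5, 1, 5, 9),             # anti-correlated
                E.1 = c(2, 2, 2, 2, 2))             # constant
  colnames(expr) <- paste0("S", 1:5)
  time_course_matrix(expr, c(Q.1 = "GQ", Q.2 = "GQ", C.1 = "GC",
                             D.1 = "GD", E.1 = "GE"))
}

test_that("cluster membership is foreign-gene, strictly above threshold", {
  m <- cluster_fixture()
  expect_warning(cl <- build_cluster("Q.1", m), "constant candidate")
  expect_equal(cl$members$transcript_id, "C.1")   # sibling Q.2 excluded
  expect_equal(cl$members$pearson_similarity, 1)
  expect_equal(cl$verdict, "unresolved")
  # threshold nobody passes
  suppressWarnings(cl2 <- build_cluster("D.1", m, sim_threshold = 0.999))
  expect_equal(nrow(cl2$members), 0)
})

test_that("constant query profiles are an error", {
  m <- cluster_fixture()
  expect_error(build_cluster("E.1", m), "constant")
})

test_that("raising the similarity threshold never adds members", {
  sc <- simulate_tapas_scenario(seed = 5)
  for (q in sc$queries[1:2]) {
    prev <- Inf
    for (thr in c(0.5, 0.7, 0.9)) {
      cl <- suppressWarnings(build_cluster(q, sc$matrix, sim_threshold = thr))
      expect_lte(nrow(cl$members), prev)
      prev <- nrow(cl$members)
    }
  }
})

test_that("functional links respect strict cutoffs per source", {
  m <- cluster_fixture()
  suppressWarnings(cl <- build_cluster("Q.1", m))
  # STRING 900 > 800 -> link
  net <- interaction_network(string = data.frame(a = "GQ", b = "GC", s = 900))
  out <- attach_links(cl, net)
  expect_equal(out$links$link_type, "string")
  expect_equal(out$verdict, "linked")
  # STRING exactly 800 -> no link
  net <- interaction_network(string = data.frame(a = "GQ", b = "GC", s = 800))
  expect_equal(attach_links(cl, net)$verdict, "unresolved")
  # experimental edge alone
  net <- interaction_network(experimental = data.frame(a = "GC", b = "GQ"))
  out <- attach_links(cl, net)
  expect_equal(out$links$link_type, "experimental")
  # GOSS link only above the (strict) cutoff
  fake <- function(g1, g2) 6.0
  expect_equal(attach_links(cl, interaction_network(), goss = fake)$verdict,
               "unresolved")
  fake_hi <- function(g1, g2) 6.01
  expect_equal(attach_links(cl, interaction_network(), goss = fake_hi)$verdict,
               "linked")
})

test_that("self-edges and out-of-range scores are rejected", {
  expect_error(interaction_network(experimental = data.frame(a = "G1", b = "G1")),
               "self-edges")
  expect_error(interaction_network(string = data.frame(a = "G1", b = "G2", s = 1200)),
               "0, 1000")
})

test_that("fallback filter means pairwise member similarity, query gene excluded", {
  # members share a specific term with IC = -log(2/8); query gene annotated
  # to a different specific term with higher IC, which must not contribute
  terms <- c("R", "A", "B")
  dag <- go_dag(terms, list(R = character(), A = "R", B = "R"),
                c(R = "BP", A = "BP", B = "BP"))
  ann <- annotation_set(list(m1 = "A", m2 = "A", q = "B",
                             b1 = "R", b2 = "R", b3 = "R", b4 = "R", b5 = "R"),
                        dag)
  ctx <- goss_context(dag, ann)
  expr <- rbind("Tq.1" = c(5, 1, 1), "Tq.2" = c(1, 5, 9),
                "Tm1.1" = c(1, 5, 9), "Tm2.1" = c(1.1, 5.2, 9.2))
  colnames(expr) <- paste0("S", 1:3)
  m <- time_course_matrix(expr, c("Tq.1" = "q", "Tq.2" = "q",
                                  "Tm1.1" = "m1", "Tm2.1" = "m2"))
  cl <- build_cluster("Tq.2", m)
  ic_a <- unname(ctx$ic["A"])  # -log(2/8)
  out <- fallback_filter(cl, ctx, mean_cutoff = ic_a - 1e-9)
  expect_equal(out$verdict, "goss_pass")
  expect_equal(out$mean_member_goss, ic_a)
  # boundary inclusive: cutoff exactly at the mean still passes
  expect_equal(fallback_filter(cl, ctx, mean_cutoff = ic_a)$verdict, "goss_pass")
  # raising the cutoff never converts discarded into a pass
  out2 <- fallback_filter(cl, ctx, mean_cutoff = ic_a + 1e-9)
  expect_equal(out2$verdict, "discarded")
})

test_that("root-only member annotation gives mean zero and a discard", {
  sc <- simulate_tapas_scenario(seed = 9)
  ctx <- goss_context(sc$dag, sc$ann)
  cl <- suppressWarnings(build_cluster(sc$decoys[1], sc$matrix))
  cl <- fallback_filter(cl, ctx)
  expect_equal(cl$verdict, "discarded")
  expect_equal(cl$mean_member_goss, 0)
})

test_that("clusters with fewer than two annotated members are discarded as such", {
  sc <- simulate_tapas_scenario(seed = 9)
  ctx <- goss_context(sc$dag, sc$ann)
  cl <- suppressWarnings(build_cluster(sc$decoys[3], sc$matrix))
  cl <- fallback_filter(cl, ctx)
  expect_equal(cl$verdict, "discarded")
  expect_equal(cl$discard_reason, "insufficient annotation")
})

test_that("fallback verdicts match a brute-force recomputation of pair means", {
  sc <- simulate_tapas_scenario(seed = 31)
  ctx <- goss_context(sc$dag, sc$ann)
  ic <- ic_table(sc$dag, sc$ann)
  for (q in c(sc$queries, sc$decoys)) {
    cl <- suppressWarnings(build_cluster(q, sc$matrix))
    out <- fallback_filter(cl, ctx)
    genes <- unique(cl$members$gene_id)
    genes <- head(genes[genes %in% ctx$annotated], 20)
    if (length(genes) < 2) {
      expect_equal(out$verdict, "discarded")
      next
    }
    vals <- c()
    for (i in seq_len(length(genes) - 1)) for (j in (i + 1):length(genes))
      vals <- c(vals, goss_gene(genes[i], genes[j], sc$ann, ic, sc$dag))
    expect_equal(out$mean_member_goss, mean(vals), tolerance = 1e-12)
    expect_equal(out$verdict, if (mean(vals) >= 2.5) "goss_pass" else "discarded")
  }
})

test_that("the full pipeline resolves planted queries and discards decoys", {
  sc <- simulate_tapas_scenario(seed = 17)
  res <- suppressWarnings(
    run_tapas(c(sc$queries, sc$decoys), sc$matrix, sc$net, sc$dag, sc$ann))
  s <- summary(res)
  planted <- s[s$query %in% sc$queries, ]
  expect_true(all(planted$verdict %in% c("linked", "goss_pass")))
  # modules with planted edges resolve via links, the rest via coherence
  expect_true(any(planted$verdict == "linked"))
  expect_true(any(planted$verdict == "goss_pass"))
  decoys <- s[s$query %in% sc$decoys, ]
  expect_true(all(decoys$verdict == "discarded"))
  # cluster membership never includes the query's own gene
  for (cl in res$clusters)
    expect_false(cl$query_gene_id %in% cl$members$gene_id)
  # edge list only references linked clusters and their best member isoforms
  expect_true(all(res$edges$query_transcript %in% s$query[s$verdict == "linked"]))
})

test_that("pipeline is deterministic and tolerant of empty or failing queries", {
  sc <- simulate_tapas_scenario(seed = 17)
  r1 <- suppressWarnings(run_tapas(sc$queries, sc$matrix, sc$net, sc$dag, sc$ann))
  r2 <- suppressWarnings(run_tapas(sc$queries, sc$matrix, sc$net, sc$dag, sc$ann))
  expect_identical(summary(r1), summary(r2))
  r0 <- run_tapas(character(), sc$matrix, sc$net, sc$dag, sc$ann)
  expect_equal(length(r0$clusters), 0)
  expect_equal(nrow(r0$edges), 0)
  expect_warning(rbad <- run_tapas("NOPE", sc$matrix, sc$net, sc$dag, sc$ann),
                 "NOPE")
  expect_equal(length(rbad$clusters), 0)
})

test_that("passed clusters sit closer to their query gene than random controls", {
  sc <- simulate_tapas_scenario(seed = 23)
  res <- suppressWarnings(
    run_tapas(c(sc$queries, sc$decoys), sc$matrix, sc$net, sc$dag, sc$ann))
  ctx <- goss_context(sc$dag, sc$ann)
  val <- validate_filtering(res$clusters, ctx, n_random = 30, seed = 23)
  expect_gt(val$median_passed, val$median_random)
  expect_lt(val$p_passed_vs_random, 0.01)
})

test_that("identical passed and control values give no signal", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(mann_whitney_one_sided(x, x), 0.5, tolerance = 1e-9)
})
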