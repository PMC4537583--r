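test_that("one-sided Fisher matches exhaustive enumeration", {
  expect_equal(fisher_one_sided(5, 0, 0, 5), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_one_sided(1, 1, 1, 1), 5 / 6, tolerance = 1e-12)
  set.seed(61)
  for (i in 1:50) {
    tb <- sample(0:8, 4, replace = TRUE)
    if ((tb[1] + tb[2]) == 0 || (tb[3] + tb[4]) == 0 ||
        (tb[1] + tb[3]) == 0 || (tb[2] + tb[4]) == 0) next
    expect_equal(fisher_one_sided(tb[1], tb[2], tb[3], tb[4]),
                 oracle_fisher(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
  }
  # a = 0: over-representation is impossible, tail includes everything
  expect_equal(fisher_one_sided(0, 5, 3, 2), 1, tolerance = 1e-12)
  expect_warning(p <- fisher_one_sided(0, 0, 3, 2), "empty margin")
  expect_equal(p, 1)
})

test_that("one-sided Mann-Whitney matches exhaustive enumeration", {
  expect_equal(mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3)), 1 / choose(6, 3),
               tolerance = 1e-12)
  set.seed(62)
  for (i in 1:30) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    vals <- sample(1000, n + m)  # untied
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    expect_equal(mann_whitney_one_sided(x, y), oracle_mann_whitney(x, y),
                 tolerance = 1e-12)
    # swapped arguments: the opposite tail, checked against the oracle too
    expect_equal(mann_whitney_one_sided(y, x), oracle_mann_whitney(y, x),
                 tolerance = 1e-12)
  }
  expect_warning(p <- mann_whitney_one_sided(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(p, 0.5)
})

test_that("large or tied samples use the tie-corrected normal tail", {
  set.seed(63)
  x <- rnorm(30, 1); y <- rnorm(40)
  expect_equal(mann_whitney_one_sided(x, y),
               stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                                  correct = FALSE)$p.value)
  expect_equal(mann_whitney_one_sided(c(1, 2, 2, 3), c(1, 1, 2, 4)),
               stats::wilcox.test(c(1, 2, 2, 3), c(1, 1, 2, 4),
                                  alternative = "greater", exact = FALSE,
                                  correct = FALSE)$p.value)
})

test_that("BH correction matches the step-up closed form", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.5), 0.5)
  expect_equal(bh_correct(c(1, 1)), c(1, 1))
  set.seed(64)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_correct(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # monotone step-up transform: q ordering follows p ordering
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("GO enrichment skips small terms and ranks a fully hit term first", {
  set.seed(65)
  # 100-gene universe; term A covers 15 genes, term B only 9
  terms <- c("R", "A", "B")
  dag <- go_dag(terms, list(R = character(), A = "R", B = "R"),
                c(R = "BP", A = "BP", B = "BP"))
  genes <- sprintf("g%03d", 1:100)
  ann <- c(lapply(stats::setNames(genes[1:15], genes[1:15]), function(g) "A"),
           lapply(stats::setNames(genes[16:24], genes[16:24]), function(g) "B"),
           lapply(stats::setNames(genes[25:100], genes[25:100]), function(g) "R"))
  ann <- annotation_set(ann, dag)
  # the root term spans the whole universe: its empty-margin warning is expected
  res <- suppressWarnings(go_enrichment(genes[1:15], genes, dag, ann,
                                        min_term_size = 10))
  expect_false("B" %in% res$term)          # fewer than 10 background genes
  expect_equal(res$term[1], "A")
  expect_equal(res$p[1], fisher_one_sided(15, 0, 0, 85), tolerance = 1e-12)
  expect_equal(nrow(go_enrichment(character(), genes, dag, ann)), 0)
  expect_error(go_enrichment("nope", genes, dag, ann), "subset")
})

test_that("random study sets produce essentially no BH discoveries", {
  set.seed(66)
  terms <- c("R", paste0("T", 1:6))
  parents <- c(list(R = character()),
               stats::setNames(lapply(1:6, function(i) "R"), paste0("T", 1:6)))
  dag <- go_dag(terms, parents, stats::setNames(rep("BP", 7), terms))
  genes <- sprintf("g%03d", 1:120)
  ann <- annotation_set(
    lapply(stats::setNames(genes, genes),
           function(g) sample(paste0("T", 1:6), 1)), dag)
  hits <- 0; tests <- 0
  for (s in 1:100) {
    study <- sample(genes, 20)
    res <- suppressWarnings(go_enrichment(study, genes, dag, ann))
    hits <- hits + sum(res$q < 0.05)
    tests <- tests + nrow(res)
  }
  expect_lt(hits / max(tests, 1), 0.02)
})

test_that("TS permutation preserves the score multiset and flags planted shifts", {
  set.seed(67)
  ts <- stats::setNames(runif(40), sprintf("g%02d", 1:40))
  events <- data.frame(gene_id = names(ts)[1:20],
                       kind = rep(c("exon_gain", "intron_retention"), 10))
  # permutation invariance of the multiset: shuffle by hand and compare
  perm <- sample(unname(ts))
  expect_setequal(round(perm, 12), round(unname(ts), 12))
  # planted fixture: exon-gain genes carry the largest TS scores
  ts2 <- ts
  gain_genes <- events$gene_id[events$kind == "exon_gain"]
  ts2[gain_genes] <- ts2[gain_genes] + 1
  out <- permute_ts_null(ts2, events, n_perm = 1000, seed = 5)
  expect_lt(out$exon_gain$p_greater, 0.01)
  expect_equal(length(out$exon_gain$null), 1000)
  expect_error(permute_ts_null(ts, events, n_perm = 0), "n_perm")
})

test_that("null fixtures yield uniform empirical permutation p-values", {
  set.seed(68)
  pvals <- vapply(1:200, function(s) {
    ts <- stats::setNames(runif(30), sprintf("g%02d", 1:30))
    ev <- data.frame(gene_id = sample(names(ts), 12), kind = "exon_gain")
    permute_ts_null(ts, ev, n_perm = 99, seed = s)$exon_gain$p_greater
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Euclidean matching is injective, greedy and deterministic", {
  profiles <- rbind(H1 = c(10, 0), H2 = c(8, 0),
                    C1 = c(10, 0), C2 = c(8, 0), C3 = c(0, 50))
  # exact copies available: both matched at distance zero
  m <- euclidean_match(c("H1", "H2"), c("C1", "C2", "C3"), profiles)
  expect_equal(m$distance, c(0, 0))
  expect_equal(m$control_gene[m$high_ts_gene == "H1"], "C1")
  # competition: first-processed (highest total) takes the shared nearest
  profiles2 <- rbind(H1 = c(10, 0), H2 = c(9, 0), C1 = c(9.6, 0), C2 = c(5, 0))
  m2 <- euclidean_match(c("H1", "H2"), c("C1", "C2"), profiles2)
  expect_equal(m2$control_gene[m2$high_ts_gene == "H1"], "C1")
  expect_equal(m2$control_gene[m2$high_ts_gene == "H2"], "C2")
  expect_error(euclidean_match(c("H1", "H2"), "C1", profiles2), "exhausted")
  expect_error(euclidean_match("H1", c("H1", "C1"), profiles2), "high-TS")
})

test_that("greedy matching passes the replay certificate on random fixtures", {
  set.seed(69)
  for (rep in 1:5) {
    n_hi <- 10; n_pool <- 25
    profiles <- matrix(runif((n_hi + n_pool) * 6, 0, 20), ncol = 6)
    rownames(profiles) <- c(sprintf("H%02d", 1:n_hi), sprintf("C%02d", 1:n_pool))
    hi <- rownames(profiles)[1:n_hi]; pool <- rownames(profiles)[-(1:n_hi)]
    m <- euclidean_match(hi, pool, profiles)
    expect_false(anyDuplicated(m$control_gene) > 0)
    # replay: at each step the assigned distance is minimal among then-unused
    used <- character()
    for (i in seq_len(nrow(m))) {
      avail <- setdiff(pool, used)
      d <- vapply(avail, function(g)
        sqrt(sum((profiles[m$high_ts_gene[i], ] - profiles[g, ])^2)), numeric(1))
      expect_lte(m$distance[i], min(d) + 1e-12)
      used <- c(used, m$control_gene[i])
    }
  }
})

test_that("stratified enrichment restricts the universe as specified", {
  labels <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    high_ts = rep(c(TRUE, FALSE), each = 20),
    essential = c(rep(TRUE, 15), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 15)),
    singleton = rep(c(TRUE, FALSE), 20))
  full <- stratified_enrichment(labels, "essential", "high_ts")
  expect_equal(c(full$a, full$b, full$c, full$d), c(15, 5, 5, 15))
  sub <- stratified_enrichment(labels, "essential", "high_ts",
                               subset = list(singleton = TRUE))
  manual <- labels[labels$singleton, ]
  expect_equal(sub$a, sum(manual$high_ts & manual$essential))
  expect_equal(sub$a + sub$b + sub$c + sub$d, nrow(manual))
  empty <- stratified_enrichment(labels, "essential", "high_ts",
                                 subset = rep(FALSE, nrow(labels)))
  expect_true(empty$flagged)
  expect_equal(empty$p, 1)
})

test_that("a planted confounder explains away the enrichment in its stratum", {
  # essentiality driven entirely by a DBD domain that also drives high-TS
  set.seed(70)
  n <- 200
  dbd <- rep(c(TRUE, FALSE), c(60, 140))
  labels <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    dbd = dbd,
    essential = ifelse(dbd, runif(n) < 0.9, runif(n) < 0.1),
    high_ts = ifelse(dbd, runif(n) < 0.8, runif(n) < 0.2))
  naive <- stratified_enrichment(labels, "essential", "high_ts")
  expect_lt(naive$p, 0.01)
  controlled <- stratified_enrichment(labels, "essential", "high_ts",
                                      subset = list(dbd = FALSE))
  expect_gt(controlled$p, 0.05)
})

test_that("gene label tables spread long TSVs into logical flags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tessential\t1", "g1\tsingleton\t0", "g2\tessential\t0"), path)
  lab <- load_gene_labels(path)
  expect_equal(lab$essential, c(TRUE, FALSE))
  expect_equal(lab$singleton, c(FALSE, NA))
})

test_that("gene profiles sum isoform FPKM per stage", {
  m <- toy_matrix()
  gp <- gene_profiles(m)
  expect_equal(unname(gp["GA", ]), unname(m$expr["TA.1", ] + m$expr["TA.2", ]))
})
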