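# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (closed forms, exhaustive enumeration, O(n^2) scans)
# and never call the code paths they check.

# Singular values of the 2 x T profile matrix from the eigenvalues of the
# 2 x 2 Gram matrix X X^t; TS score in closed form.
oracle_ts <- function(p, q) {
  X <- rbind(p, q)
  ev <- eigen(X %*% t(X), symmetric = TRUE, only.values = TRUE)$values
  s <- sqrt(pmax(ev, 0))
  2 * (1 - max(s) / sum(s))
}

# Brute-force splice-event scan: all-pairs interval overlap, no IRanges.
oracle_events <- function(primary, minor) {
  pex <- primary$exons; mex <- minor$exons
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  out <- list()
  for (i in seq_len(nrow(mex))) {
    hit <- FALSE
    for (j in seq_len(nrow(pex)))
      if (overlaps(mex[i, 1], mex[i, 2], pex[j, 1], pex[j, 2])) hit <- TRUE
    if (!hit)
      out[[length(out) + 1L]] <- c("exon_gain", mex[i, 1], mex[i, 2])
  }
  if (nrow(pex) > 1L) {
    for (j in seq_len(nrow(pex) - 1L)) {
      is <- pex[j, 2] + 1L; ie <- pex[j + 1L, 1] - 1L
      for (i in seq_len(nrow(mex)))
        if (mex[i, 1] <= is && mex[i, 2] >= ie)
          out[[length(out) + 1L]] <- c("intron_retention", is, ie)
    }
  }
  if (!length(out))
    return(data.frame(kind = character(), start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(kind = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
             stringsAsFactors = FALSE)
}

# canonical sort for event-set comparison
event_key <- function(ev) sort(paste(ev$kind, ev$start, ev$end))

# Random DAG + annotation fixture for Resnik cross-checks.
random_go_fixture <- function(n_terms = 20, n_genes = 30, seed = 1) {
  set.seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- list()
  parents[[terms[1]]] <- character()
  for (i in 2:n_terms)
    parents[[terms[i]]] <- sample(terms[seq_len(i - 1L)],
                                  sample(1:min(2L, i - 1L), 1L))
  dag <- tapasTS::go_dag(terms, parents,
                         stats::setNames(rep("BP", n_terms), terms))
  genes <- sprintf("g%03d", seq_len(n_genes))
  ann <- lapply(stats::setNames(genes, genes), function(g)
    sample(terms, sample(1:3, 1L)))
  list(dag = dag, ann = suppressWarnings(tapasTS::annotation_set(ann, dag)),
       terms = terms, genes = genes, raw_parents = parents)
}

# Naive transitive closure over is_a edges (term included in its own set
# only where stated by the caller).
oracle_ancestors <- function(term, parents) {
  anc <- character(); frontier <- parents[[term]]
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), anc)
  }
  anc
}

# Naive IC: per-gene propagated term sets counted by direct looping.
oracle_ic <- function(fix) {
  prop <- lapply(fix$ann$annotations, function(ts)
    unique(c(ts, unlist(lapply(ts, oracle_ancestors, fix$raw_parents)))))
  n <- length(prop)
  counts <- vapply(fix$terms, function(t)
    sum(vapply(prop, function(s) t %in% s, logical(1))), numeric(1))
  ic <- -log(counts[counts > 0] / n)
  list(ic = ic, prop = prop)
}

# Naive Resnik: enumerate common ancestors explicitly.
oracle_resnik <- function(t1, t2, ic, parents) {
  common <- intersect(c(t1, oracle_ancestors(t1, parents)),
                      c(t2, oracle_ancestors(t2, parents)))
  common <- common[common %in% names(ic)]
  if (!length(common)) 0 else max(ic[common])
}

# Naive gene-pair Resnik: max over all direct-annotation term pairs.
oracle_goss_gene <- function(g1, g2, fix, ic) {
  best <- 0
  for (t1 in fix$ann$annotations[[g1]])
    for (t2 in fix$ann$annotations[[g2]])
      best <- max(best, oracle_resnik(t1, t2, ic, fix$raw_parents))
  best
}

# Exhaustive hypergeometric tail for the one-sided Fisher test.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(N, c1)
  sum(probs[ks >= a])
}

# Exhaustive Mann-Whitney: enumerate every assignment of the pooled values
# to the x positions; one-sided tail for "x stochastically greater".
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y); n <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  obs <- u_stat(x, y)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  mean(us >= obs - 1e-12)
}

# Closed-form step-up BH.
oracle_bh <- function(p) {
  m <- length(p); o <- order(p); q <- numeric(m)
  sorted <- p[o]
  qs <- pmin(1, sorted * m / seq_len(m))
  qs <- rev(cummin(rev(qs)))
  q[o] <- qs
  q
}

# Rank-based AUC for separating planted switch isoforms from the rest.
rank_auc <- function(pos, neg) mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))

# Small designated two-isoform fixture used across tests.
toy_matrix <- function() {
  expr <- rbind(TA.1 = c(10, 8, 2, 1), TA.2 = c(1, 2, 8, 10),
                TB.1 = c(5, 5, 4, 6),  TB.2 = c(10, 10, 8, 12))
  colnames(expr) <- paste0("S", 1:4)
  time_course_matrix(expr, c(TA.1 = "GA", TA.2 = "GA",
                             TB.1 = "GB", TB.2 = "GB"))
}
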