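#' One-sided Fisher's exact test for a 2x2 table
#'
#' Tests over-representation of the top-left cell: the p-value is the
#' hypergeometric upper tail P(X >= a) at the observed margins. Any empty
#' margin makes enrichment untestable; by convention p = 1 with a warning.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` = in study and in
#'   category, `b` = in study only, `c` = in category only, `d` = neither.
#' @return One-sided p-value.
#' @examples
#' fisher_one_sided(5, 0, 0, 5)  # 1 / choose(10, 5)
#' @export
fisher_one_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("empty margin: enrichment untestable, p = 1")
    return(1)
  }
  stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                     alternative = "greater")$p.value
}

#' One-sided Mann-Whitney rank test
#'
#' Tests whether `x` is stochastically greater than `y`. The exact null
#' distribution is enumerated for small untied samples (min(n, m) <= 8 and
#' n + m <= 20); otherwise the tie-corrected normal approximation (without
#' continuity correction, so identical samples give p = 0.5) is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return One-sided p-value.
#' @export
mann_whitney_one_sided <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical: p = 0.5 by convention")
    return(0.5)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8L &&
    (length(x) + length(y)) <= 20L
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = FALSE)$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate correction: q_i = min over j with
#' p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_correct <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' GO term enrichment of a study set
#'
#' Per-term one-sided Fisher's exact test of the study genes against the
#' background universe, on true-path-propagated annotations. Terms with
#' fewer than `min_term_size` annotated genes in the background are not
#' tested ("less than" - a term with exactly `min_term_size` genes is
#' tested). Benjamini-Hochberg correction is applied over the tested terms.
#'
#' @param study Character vector of study genes (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param dag,ann [go_dag()] and [annotation_set()].
#' @param namespace GO namespace (default `"BP"`).
#' @param min_term_size Minimum background annotation count; default 10.
#' @return `data.frame` (term, a, b, c, d, p, q) sorted by p; zero rows for
#'   an empty study set.
#' @export
go_enrichment <- function(study, background, dag, ann, namespace = "BP",
                          min_term_size = 10) {
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  empty <- data.frame(term = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  if (!length(study)) return(empty)
  sets <- propagate_annotations(dag, ann, namespace = namespace)
  sets <- lapply(sets, intersect, background)
  n_bg <- vapply(sets, length, 1L)
  testable <- names(sets)[n_bg >= min_term_size]
  if (!length(testable)) return(empty)
  rows <- lapply(testable, function(t) {
    a <- length(intersect(study, sets[[t]]))
    b <- length(study) - a
    c <- n_bg[[t]] - a
    d <- length(background) - a - b - c
    data.frame(term = t, a = a, b = b, c = c, d = d,
               p = fisher_one_sided(a, b, c, d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_correct(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Permutation null for TS scores across splice-event classes
#'
#' Gene-level TS scores are randomly permuted across genes while the event
#' annotations stay fixed, giving a null distribution for the median TS
#' shift of each event kind (observed statistic: median TS of genes with
#' the event minus median TS of genes without). Empirical one-sided
#' p-values are computed as (r + 1) / (n_perm + 1), so they are never zero.
#'
#' @param ts_by_gene Named numeric vector gene -> TS score (>= 2 genes).
#' @param events_by_gene `data.frame` with columns `gene_id` and `kind`, or
#'   a named list gene -> character vector of kinds.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @return Object of class `ts_perm_null`: per kind, the observed median
#'   shift, the null distribution, and `p_greater` / `p_less`.
#' @export
permute_ts_null <- function(ts_by_gene, events_by_gene, n_perm, seed = 1) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(ts_by_gene) < 2L) stop("need >= 2 genes")
  if (is.data.frame(events_by_gene)) {
    kinds_of <- split(as.character(events_by_gene$kind),
                      as.character(events_by_gene$gene_id))
  } else kinds_of <- events_by_gene
  genes <- names(ts_by_gene)
  kinds <- sort(unique(unlist(kinds_of)))
  has_kind <- lapply(stats::setNames(kinds, kinds), function(k)
    genes %in% names(kinds_of)[vapply(kinds_of, function(v) k %in% v, logical(1))])
  shift <- function(ts, idx) {
    if (!any(idx) || all(idx)) return(NA_real_)
    stats::median(ts[idx]) - stats::median(ts[!idx])
  }
  set.seed(seed)
  ts <- unname(ts_by_gene)
  null <- matrix(NA_real_, n_perm, length(kinds), dimnames = list(NULL, kinds))
  for (i in seq_len(n_perm)) {
    perm <- sample(ts)
    for (k in kinds) null[i, k] <- shift(perm, has_kind[[k]])
  }
  out <- lapply(stats::setNames(kinds, kinds), function(k) {
    obs <- shift(ts, has_kind[[k]])
    nk <- null[, k]
    list(observed = obs, null = nk,
         p_greater = (sum(nk >= obs) + 1) / (n_perm + 1),
         p_less = (sum(nk <= obs) + 1) / (n_perm + 1))
  })
  structure(out, class = "ts_perm_null")
}

#' @export
print.ts_perm_null <- function(x, ...) {
  cat("TS permutation null (", length(x[[1]]$null), " permutations)\n", sep = "")
  for (k in names(x))
    cat(sprintf("  %-18s observed shift %+.4f  p_greater %.4g  p_less %.4g\n",
                k, x[[k]]$observed, x[[k]]$p_greater, x[[k]]$p_less))
  invisible(x)
}

#' Euclidean-matched control genes for high-TS genes
#'
#' Bias-control pairing: each high-TS gene is matched to the control-pool
#' gene with the closest gene-level expression profile (Euclidean
#' distance), iteratively, so a control gene is used at most once. High-TS
#' genes are processed in a deterministic order - decreasing total
#' expression, ties broken lexicographically - and distance ties are broken
#' lexicographically by control gene id.
#'
#' @param high_ts Character vector of high-TS gene ids.
#' @param pool Character vector of candidate control genes (disjoint from
#'   `high_ts`, at least as many as `high_ts`).
#' @param gene_profiles Numeric matrix of gene-level (isoform-summed)
#'   expression profiles, rownames covering both sets.
#' @return `data.frame` (high_ts_gene, control_gene, distance); the mapping
#'   is injective.
#' @seealso [gene_profiles()] to build the matrix from a
#'   [time_course_matrix()].
#' @export
euclidean_match <- function(high_ts, pool, gene_profiles) {
  if (length(intersect(high_ts, pool)))
    stop("control pool must not contain high-TS genes")
  if (length(pool) < length(high_ts)) stop("control pool exhausted")
  need <- setdiff(c(high_ts, pool), rownames(gene_profiles))
  if (length(need)) stop("missing gene profiles: ", paste(need, collapse = ", "))
  totals <- rowSums(gene_profiles[high_ts, , drop = FALSE])
  order_hi <- high_ts[order(-totals, high_ts)]
  unused <- sort(pool)
  rows <- vector("list", length(order_hi))
  for (i in seq_along(order_hi)) {
    g <- order_hi[i]
    dd <- sqrt(colSums((t(gene_profiles[unused, , drop = FALSE]) -
                          gene_profiles[g, ])^2))
    j <- which.min(dd)   # ties: first in lexicographic order
    rows[[i]] <- data.frame(high_ts_gene = g, control_gene = unused[j],
                            distance = unname(dd[j]), stringsAsFactors = FALSE)
    unused <- unused[-j]
  }
  do.call(rbind, rows)
}

#' Gene-level expression profiles
#'
#' Sums all isoform FPKM vectors of each gene per stage - the standard FPKM
#' aggregation to gene level.
#'
#' @param m A [time_course_matrix()].
#' @return Numeric matrix, genes in rows, stages in columns.
#' @export
gene_profiles <- function(m) {
  stopifnot(inherits(m, "TimeCourseMatrix"))
  rowsum(m$expr, group = m$transcript_to_gene)
}

#' Enrichment within a stratum of the gene universe
#'
#' Re-runs the one-sided Fisher test for `outcome` vs `group` inside the
#' sub-universe selected by `subset` - e.g. only singleton genes, or
#' signalling/DBD-domain genes removed, or only genes of age Metazoa or
#' older. Genes with `NA` in the outcome or group flag are excluded. A
#' stratum with any empty margin is untestable and flagged with p = 1.
#'
#' @param labels `data.frame` with a `gene_id` column and logical flag
#'   columns (externally supplied properties such as `essential`,
#'   `singleton`, `high_ts`, domain flags, age classes).
#' @param outcome Name of the flag tested for enrichment.
#' @param group Name of the flag defining the study group (e.g.
#'   `"high_ts"`).
#' @param subset Optional stratum: a logical vector over rows of `labels`,
#'   or a named list of required flag values, e.g.
#'   `list(singleton = TRUE, dbd = FALSE)`.
#' @return One-row `data.frame` (category, a, b, c, d, p, flagged).
#' @export
stratified_enrichment <- function(labels, outcome, group, subset = NULL) {
  stopifnot(is.data.frame(labels), "gene_id" %in% names(labels))
  keep <- rep(TRUE, nrow(labels))
  if (is.logical(subset)) {
    keep <- subset
  } else if (is.list(subset)) {
    for (nm in names(subset))
      keep <- keep & !is.na(labels[[nm]]) & labels[[nm]] == subset[[nm]]
  }
  sub <- labels[keep & !is.na(labels[[outcome]]) & !is.na(labels[[group]]), ,
                drop = FALSE]
  a <- sum(sub[[group]] & sub[[outcome]])
  b <- sum(sub[[group]] & !sub[[outcome]])
  c <- sum(!sub[[group]] & sub[[outcome]])
  d <- sum(!sub[[group]] & !sub[[outcome]])
  flagged <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  p <- if (flagged) 1 else fisher_one_sided(a, b, c, d)
  data.frame(category = paste0(outcome, "|", group), a = a, b = b, c = c,
             d = d, p = p, flagged = flagged, stringsAsFactors = FALSE)
}

#' Read a gene label table
#'
#' Long-format TSV `gene_id<TAB>flag_name<TAB>0/1`, spread to one logical
#' column per flag; genes missing a flag get `NA` (unknown).
#'
#' @param path TSV path (no header required; a `gene_id` header row is
#'   tolerated).
#' @return `data.frame` with `gene_id` plus one logical column per flag.
#' @export
load_gene_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "gene_id")) tab <- tab[-1, , drop = FALSE]
  names(tab) <- c("gene_id", "flag", "value")
  genes <- sort(unique(tab$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (f in sort(unique(tab$flag))) {
    sub <- tab[tab$flag == f, ]
    out[[f]] <- NA
    out[[f]][match(sub$gene_id, genes)] <- as.integer(sub$value) == 1L
  }
  out
}
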