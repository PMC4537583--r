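pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct an interaction network
#'
#' Holds experimentally determined protein-protein interaction edges and
#' STRING-style scored edges (0-1000 integer scale), both as unordered gene
#' pairs. Self-edges are rejected.
#'
#' @param experimental `data.frame` (or 2-column matrix) with gene pair
#'   columns, or `NULL`.
#' @param string `data.frame` with columns geneA, geneB, score (0-1000), or
#'   `NULL`.
#' @return Object of class `InteractionNetwork`.
#' @export
interaction_network <- function(experimental = NULL, string = NULL) {
  exp_keys <- character()
  if (!is.null(experimental) && NROW(experimental)) {
    a <- as.character(experimental[[1L]]); b <- as.character(experimental[[2L]])
    if (any(a == b)) stop("self-edges are not allowed")
    exp_keys <- unique(pair_key(a, b))
  }
  str_scores <- stats::setNames(numeric(), character())
  if (!is.null(string) && NROW(string)) {
    a <- as.character(string[[1L]]); b <- as.character(string[[2L]])
    s <- as.numeric(string[[3L]])
    if (any(a == b)) stop("self-edges are not allowed")
    if (any(s < 0 | s > 1000)) stop("STRING scores must lie in [0, 1000]")
    k <- pair_key(a, b)
    # keep the best score per unordered pair
    ord <- order(k, -s)
    k <- k[ord]; s <- s[ord]
    first <- !duplicated(k)
    str_scores <- stats::setNames(s[first], k[first])
  }
  structure(list(experimental = exp_keys, string = str_scores),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork:", length(x$experimental), "experimental edges,",
      length(x$string), "STRING edges\n")
  invisible(x)
}

#' Build a co-expression cluster around a query isoform
#'
#' Collects every transcript from *other* genes whose expression profile
#' has Pearson correlation strictly greater than `sim_threshold` with the
#' query isoform's profile. Transcripts of the query's own gene are never
#' members. Members are sorted by decreasing similarity, ties broken by
#' transcript id. Constant candidate profiles (undefined correlation) are
#' skipped with one summarising warning.
#'
#' @param query Query transcript id (must be a row of `m` with a
#'   non-constant profile).
#' @param m A [time_course_matrix()].
#' @param sim_threshold Pearson similarity cut (strict `>`); default 0.7.
#' @return Object of class `TapasCluster` with `query_transcript_id`,
#'   `query_gene_id`, `members` (data.frame transcript_id, gene_id,
#'   pearson_similarity), empty `links`, `verdict = "unresolved"`.
#' @export
build_cluster <- function(query, m, sim_threshold = 0.7) {
  stopifnot(inherits(m, "TimeCourseMatrix"))
  if (!query %in% rownames(m$expr)) stop("query transcript not in matrix: ", query)
  qp <- m$expr[query, ]
  if (stats::sd(qp) == 0) stop("query profile is constant: ", query)
  qgene <- unname(m$transcript_to_gene[[query]])
  foreign <- rownames(m$expr)[m$transcript_to_gene != qgene]
  members <- data.frame(transcript_id = character(), gene_id = character(),
                        pearson_similarity = numeric(), stringsAsFactors = FALSE)
  if (length(foreign)) {
    sub <- m$expr[foreign, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0))
      warning("skipping ", sum(sds == 0), " constant candidate profile(s)")
    foreign <- foreign[sds > 0]
    if (length(foreign)) {
      r <- as.vector(stats::cor(qp, t(m$expr[foreign, , drop = FALSE])))
      keep <- r > sim_threshold
      members <- data.frame(transcript_id = foreign[keep],
                            gene_id = unname(m$transcript_to_gene[foreign[keep]]),
                            pearson_similarity = r[keep], stringsAsFactors = FALSE)
      members <- members[order(-members$pearson_similarity, members$transcript_id), ,
                         drop = FALSE]
      rownames(members) <- NULL
    }
  }
  structure(list(query_transcript_id = query, query_gene_id = qgene,
                 members = members,
                 links = data.frame(member_gene = character(),
                                    link_type = character(), score = numeric(),
                                    stringsAsFactors = FALSE),
                 verdict = "unresolved", mean_member_goss = NA_real_,
                 sim_threshold = sim_threshold),
            class = "TapasCluster")
}

#' @export
print.TapasCluster <- function(x, ...) {
  cat("TapasCluster for", x$query_transcript_id, "(gene", x$query_gene_id, ")\n")
  cat("  members:", nrow(x$members), "transcripts from",
      length(unique(x$members$gene_id)), "genes (r >", x$sim_threshold, ")\n")
  cat("  links:", nrow(x$links),
      if (nrow(x$links)) paste0("(", paste(unique(x$links$link_type), collapse = ", "), ")") else "",
      "\n")
  cat("  verdict:", x$verdict,
      if (!is.na(x$mean_member_goss)) paste0("(mean member GOSS ",
                                             signif(x$mean_member_goss, 4), ")") else "",
      "\n")
  invisible(x)
}

#' Attach functional links between the query gene and cluster members
#'
#' For each member gene a link is recorded when the (query gene, member
#' gene) pair has an experimental interaction, a STRING score strictly
#' above `string_cutoff`, or a gene-pair Resnik similarity strictly above
#' `goss_cutoff`. The cluster verdict becomes `"linked"` when at least one
#' link exists, otherwise it stays `"unresolved"` pending
#' [fallback_filter()].
#'
#' @param cluster A [build_cluster()] result.
#' @param net An [interaction_network()].
#' @param goss Either `NULL` or a gene-pair scorer `function(g1, g2)`
#'   returning a similarity or `NA` (see [goss_context()]`$score`).
#' @param string_cutoff STRING score cut (strict `>`); default 800.
#' @param goss_cutoff Similarity cut for highly specific GO links (strict
#'   `>`); default 6.
#' @return The cluster with `links` and `verdict` updated.
#' @export
attach_links <- function(cluster, net, goss = NULL,
                         string_cutoff = 800, goss_cutoff = 6.0) {
  stopifnot(inherits(cluster, "TapasCluster"), inherits(net, "InteractionNetwork"))
  qg <- cluster$query_gene_id
  links <- list()
  for (g in unique(cluster$members$gene_id)) {
    k <- pair_key(qg, g)
    if (k %in% net$experimental)
      links[[length(links) + 1L]] <- data.frame(member_gene = g,
                                                link_type = "experimental",
                                                score = NA_real_)
    s <- net$string[k]
    if (!is.na(s) && s > string_cutoff)
      links[[length(links) + 1L]] <- data.frame(member_gene = g,
                                                link_type = "string",
                                                score = unname(s))
    if (!is.null(goss)) {
      v <- goss(qg, g)
      if (!is.na(v) && v > goss_cutoff)
        links[[length(links) + 1L]] <- data.frame(member_gene = g,
                                                  link_type = "goss",
                                                  score = v)
    }
  }
  cluster$links <- if (length(links)) do.call(rbind, links) else cluster$links
  if (nrow(cluster$links)) cluster$verdict <- "linked"
  cluster
}

#' Average-similarity fallback filter
#'
#' For clusters with no direct functional link: take the `k` most-similar
#' member genes that carry GO terms in the working namespace (the query's
#' own gene is never among them), compute the arithmetic mean of the
#' gene-pair Resnik similarity over all unordered pairs of those genes, and
#' pass the cluster (`verdict = "goss_pass"`) when the mean reaches
#' `mean_cutoff`, otherwise discard it. The comparison is `>=` (boundary
#' inclusive). Fewer than two annotated member genes means the coherence of
#' the cluster cannot be assessed: the cluster is discarded with reason
#' `"insufficient annotation"`.
#'
#' @param cluster A [attach_links()] result (clusters already `"linked"`
#'   are returned unchanged).
#' @param ctx A [goss_context()].
#' @param k Number of closest annotated member genes to use; default 20.
#' @param mean_cutoff Mean-similarity cut; default 2.5, far above the
#'   random background expected from unrelated gene pairs.
#' @return The cluster with `verdict` (`"goss_pass"` or `"discarded"`),
#'   `mean_member_goss` and possibly `discard_reason` filled in.
#' @export
fallback_filter <- function(cluster, ctx, k = 20, mean_cutoff = 2.5) {
  stopifnot(inherits(cluster, "TapasCluster"))
  if (cluster$verdict == "linked") return(cluster)
  mem <- cluster$members          # already sorted by similarity
  genes <- mem$gene_id[!duplicated(mem$gene_id)]
  genes <- genes[genes %in% ctx$annotated]
  genes <- utils::head(genes, k)
  if (length(genes) < 2L) {
    cluster$verdict <- "discarded"
    cluster$discard_reason <- "insufficient annotation"
    return(cluster)
  }
  prs <- utils::combn(genes, 2L)
  vals <- mapply(ctx$score, prs[1L, ], prs[2L, ])
  cluster$mean_member_goss <- mean(vals)
  if (cluster$mean_member_goss >= mean_cutoff) {
    cluster$verdict <- "goss_pass"
  } else {
    cluster$verdict <- "discarded"
    cluster$discard_reason <- "low mean member GOSS"
  }
  cluster
}

#' Validate the TAPAS filtering step
#'
#' Computes, for each cluster, the mean gene-pair Resnik similarity between
#' its member genes and the query isoform's parent gene, and compares the
#' distribution for clusters that passed (verdict `linked` or `goss_pass`)
#' against discarded clusters and against a random-membership control:
#' clusters with the same sizes and queries but members drawn uniformly
#' from the annotated gene universe (seeded). Reports group medians and a
#' one-sided Mann-Whitney p-value for passed > random.
#'
#' @param clusters List of processed `TapasCluster`s.
#' @param ctx A [goss_context()].
#' @param n_random Number of random control clusters; default 100.
#' @param seed RNG seed for the control draw.
#' @return Object of class `tapas_validation`: per-cluster scores, group
#'   medians, and `p_passed_vs_random`.
#' @export
validate_filtering <- function(clusters, ctx, n_random = 100, seed = 1) {
  stopifnot(length(clusters) >= 1L)
  query_goss <- function(qgene, member_genes) {
    member_genes <- intersect(unique(member_genes), ctx$annotated)
    if (!length(member_genes) || !(qgene %in% ctx$annotated)) return(NA_real_)
    mean(vapply(member_genes, function(g) ctx$score(qgene, g), numeric(1)))
  }
  obs <- data.frame(
    query = vapply(clusters, `[[`, character(1), "query_transcript_id"),
    verdict = vapply(clusters, `[[`, character(1), "verdict"),
    mean_query_goss = vapply(clusters, function(cl)
      query_goss(cl$query_gene_id, cl$members$gene_id), numeric(1)),
    stringsAsFactors = FALSE)
  passed <- obs$mean_query_goss[obs$verdict %in% c("linked", "goss_pass")]
  discarded <- obs$mean_query_goss[obs$verdict == "discarded"]
  set.seed(seed)
  usable <- which(!is.na(obs$mean_query_goss) &
                    vapply(clusters, function(cl) nrow(cl$members) > 0L, logical(1)))
  random <- numeric()
  if (length(usable)) {
    pick <- sample(usable, n_random, replace = TRUE)
    random <- vapply(pick, function(i) {
      cl <- clusters[[i]]
      size <- length(unique(cl$members$gene_id))
      pool <- setdiff(ctx$annotated, cl$query_gene_id)
      query_goss(cl$query_gene_id, sample(pool, min(size, length(pool))))
    }, numeric(1))
  }
  p <- if (length(passed[!is.na(passed)]) && length(random[!is.na(random)]))
    mann_whitney_one_sided(passed[!is.na(passed)], random[!is.na(random)])
  else NA_real_
  structure(list(per_cluster = obs,
                 median_passed = stats::median(passed, na.rm = TRUE),
                 median_discarded = stats::median(discarded, na.rm = TRUE),
                 median_random = stats::median(random, na.rm = TRUE),
                 random_scores = random,
                 p_passed_vs_random = p),
            class = "tapas_validation")
}

#' @export
print.tapas_validation <- function(x, ...) {
  cat("TAPAS filtering validation (mean query-gene GOSS per cluster)\n")
  cat("  median passed:   ", signif(x$median_passed, 4), "\n")
  cat("  median discarded:", signif(x$median_discarded, 4), "\n")
  cat("  median random:   ", signif(x$median_random, 4), "\n")
  cat("  one-sided Mann-Whitney p (passed > random):",
      format.pval(x$p_passed_vs_random), "\n")
  invisible(x)
}

#' TAPAS configuration
#'
#' @param sim_threshold Pearson cut for cluster membership (strict `>`).
#' @param string_cutoff STRING score cut (strict `>`).
#' @param goss_link_cutoff Similarity cut for direct GO links (strict `>`).
#' @param goss_mean_cutoff Mean-similarity cut for the fallback filter
#'   (`>=`).
#' @param k Closest annotated member genes used by the fallback filter.
#' @param namespace GO namespace used throughout.
#' @return List of class `tapas_config`.
#' @export
tapas_config <- function(sim_threshold = 0.7, string_cutoff = 800,
                         goss_link_cutoff = 6.0, goss_mean_cutoff = 2.5,
                         k = 20, namespace = "BP") {
  structure(list(sim_threshold = sim_threshold, string_cutoff = string_cutoff,
                 goss_link_cutoff = goss_link_cutoff,
                 goss_mean_cutoff = goss_mean_cutoff, k = k,
                 namespace = namespace),
            class = "tapas_config")
}

#' Run the full TAPAS pipeline
#'
#' For each query isoform (typically the high-TS minor isoforms):
#' [build_cluster()] then [attach_links()] then [fallback_filter()]. Per-
#' query failures are logged as warnings and the pipeline continues. Emits
#' the functional-edge list between query isoforms and the best-correlated
#' member isoform of each linked gene.
#'
#' @param queries Character vector of query transcript ids.
#' @param m A [time_course_matrix()].
#' @param net An [interaction_network()].
#' @param dag,ann Ontology and annotations ([go_dag()], [annotation_set()]);
#'   may be `NULL` to skip all GO-based steps.
#' @param config A [tapas_config()].
#' @return Object of class `tapas_result`: `clusters` (named list),
#'   `edges` (data.frame query_transcript, member_transcript, link_type,
#'   score), `config`.
#' @export
run_tapas <- function(queries, m, net, dag = NULL, ann = NULL,
                      config = tapas_config()) {
  stopifnot(inherits(config, "tapas_config"))
  ctx <- if (!is.null(dag) && !is.null(ann))
    goss_context(dag, ann, namespace = config$namespace) else NULL
  clusters <- list()
  for (q in queries) {
    cl <- tryCatch({
      cl <- build_cluster(q, m, sim_threshold = config$sim_threshold)
      cl <- attach_links(cl, net, goss = if (!is.null(ctx)) ctx$score,
                         string_cutoff = config$string_cutoff,
                         goss_cutoff = config$goss_link_cutoff)
      if (cl$verdict != "linked") {
        if (!is.null(ctx)) {
          cl <- fallback_filter(cl, ctx, k = config$k,
                                mean_cutoff = config$goss_mean_cutoff)
        } else {
          cl$verdict <- "discarded"
          cl$discard_reason <- "no annotations supplied"
        }
      }
      cl
    }, error = function(e) {
      warning("query ", q, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(cl)) clusters[[q]] <- cl
  }
  edges <- list()
  for (cl in clusters) {
    if (!nrow(cl$links)) next
    for (i in seq_len(nrow(cl$links))) {
      g <- cl$links$member_gene[i]
      best <- cl$members$transcript_id[cl$members$gene_id == g][1L]
      edges[[length(edges) + 1L]] <- data.frame(
        query_transcript = cl$query_transcript_id,
        member_transcript = best,
        link_type = cl$links$link_type[i],
        score = cl$links$score[i], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(query_transcript = character(), member_transcript = character(),
               link_type = character(), score = numeric(),
               stringsAsFactors = FALSE)
  structure(list(clusters = clusters, edges = edges, config = config),
            class = "tapas_result")
}

#' @export
print.tapas_result <- function(x, ...) {
  v <- vapply(x$clusters, `[[`, character(1), "verdict")
  cat("TAPAS result:", length(x$clusters), "queries\n")
  if (length(v)) print(table(verdict = v))
  cat(nrow(x$edges), "functional edges\n")
  invisible(x)
}

#' @export
summary.tapas_result <- function(object, ...) {
  data.frame(
    query = vapply(object$clusters, `[[`, character(1), "query_transcript_id"),
    gene = vapply(object$clusters, `[[`, character(1), "query_gene_id"),
    n_members = vapply(object$clusters, function(cl) nrow(cl$members), integer(1)),
    n_links = vapply(object$clusters, function(cl) nrow(cl$links), integer(1)),
    verdict = vapply(object$clusters, `[[`, character(1), "verdict"),
    mean_member_goss = vapply(object$clusters, `[[`, numeric(1), "mean_member_goss"),
    row.names = NULL, stringsAsFactors = FALSE)
}
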