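#' Construct a GO DAG
#'
#' Directed acyclic graph of GO terms connected by is_a edges (part_of and
#' other relationship types are not traversed; is_a-only is the
#' conservative Resnik convention). Each term belongs to one namespace
#' (BP, MF or CC) and every non-root term must reach its namespace root.
#'
#' @param terms Character vector of term ids.
#' @param parents Named list: term id -> character vector of is_a parents
#'   (may be missing/empty for roots). Edges to unknown terms are dropped.
#' @param namespace Named character vector term id -> `"BP"`, `"MF"` or
#'   `"CC"`.
#' @return Object of class `GoDag` with elements `terms`, `parents`,
#'   `namespace`, `roots` (named by namespace) and `children`.
#' @export
go_dag <- function(terms, parents, namespace) {
  terms <- unique(as.character(terms))
  if (!all(terms %in% names(namespace)))
    stop("every term needs a namespace")
  namespace <- namespace[terms]
  if (!all(namespace %in% c("BP", "MF", "CC")))
    stop("namespace values must be BP, MF or CC")
  par <- lapply(stats::setNames(terms, terms), function(t) {
    p <- unique(as.character(parents[[t]]))
    p[p %in% terms & p != t]
  })
  # topological order doubles as the acyclicity check
  topo <- topo_sort(terms, par)
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) for (p in par[[t]])
    children[[p]] <- c(children[[p]], t)
  is_root <- vapply(par, length, 1L) == 0L
  roots <- stats::setNames(terms[is_root], namespace[is_root])
  structure(list(terms = terms, parents = par, namespace = namespace,
                 roots = roots, children = children, topo = topo),
            class = "GoDag")
}

topo_sort <- function(terms, parents) {
  indeg <- stats::setNames(vapply(parents, length, 1L), terms)
  kids <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) for (p in parents[[t]]) kids[[p]] <- c(kids[[p]], t)
  queue <- terms[indeg == 0L]
  out <- character()
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    out <- c(out, t)
    for (k in kids[[t]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != length(terms))
    stop("is_a graph contains a cycle")
  out
}

#' @export
print.GoDag <- function(x, ...) {
  cat("GoDag:", length(x$terms), "terms;",
      paste(names(x$roots), x$roots, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Ancestor sets of every term
#'
#' Transitive closure over is_a edges, computed once in topological order.
#' Ancestor sets do not include the term itself.
#'
#' @param dag A [go_dag()].
#' @return Named list term id -> character vector of ancestors.
#' @export
go_ancestors <- function(dag) {
  stopifnot(inherits(dag, "GoDag"))
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in dag$topo) {
    a <- character()
    for (p in dag$parents[[t]]) a <- c(a, p, anc[[p]])
    anc[[t]] <- unique(a)
  }
  anc
}

#' Read an OBO 1.2 ontology
#'
#' Minimal stanza parser retaining id, name, namespace and is_a edges.
#' Obsolete terms are dropped, along with edges pointing at them.
#'
#' @param path OBO file path.
#' @return A [go_dag()].
#' @export
load_obo <- function(path) {
  lines <- readLines(path)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) if (!is.null(cur) && !isTRUE(cur$obsolete) &&
                             !is.null(cur$id)) terms[[cur$id]] <<- cur
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(cur); cur <- list(is_a = character()); in_term <- TRUE; next }
    if (startsWith(ln, "[")) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "namespace:"))
      cur$namespace <- ns_map[trimws(sub("^namespace:", "", ln))]
    else if (startsWith(ln, "is_a:"))
      cur$is_a <- c(cur$is_a, trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
    else if (startsWith(ln, "is_obsolete:"))
      cur$obsolete <- grepl("true", ln)
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
  }
  flush(cur)
  if (!length(terms)) stop("no [Term] stanzas in ", path)
  ids <- names(terms)
  ns <- vapply(terms, function(t) t$namespace %||% NA_character_, character(1))
  if (anyNA(ns)) stop("term(s) without namespace in ", path)
  go_dag(ids, lapply(terms, `[[`, "is_a"), stats::setNames(ns, ids))
}

#' Construct an annotation set
#'
#' Direct gene-to-term annotations. Term ids absent from the DAG are
#' dropped with a warning. ND-evidence and NOT-qualified rows are assumed
#' already removed ([load_gaf()] does this).
#'
#' @param annotations Named list: gene id -> character vector of term ids.
#' @param dag A [go_dag()] used to validate term ids.
#' @return Object of class `AnnotationSet` with element `annotations`.
#' @export
annotation_set <- function(annotations, dag) {
  stopifnot(inherits(dag, "GoDag"))
  ann <- lapply(annotations, function(ts) unique(as.character(ts)))
  unknown <- setdiff(unique(unlist(ann)), dag$terms)
  if (length(unknown)) {
    warning("dropping annotation(s) to ", length(unknown),
            " term(s) absent from the ontology: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    ann <- lapply(ann, function(ts) ts[!ts %in% unknown])
  }
  ann <- ann[vapply(ann, length, 1L) > 0L]
  structure(list(annotations = ann), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", length(x$annotations), "genes,",
      length(unique(unlist(x$annotations))), "distinct terms\n")
  invisible(x)
}

#' Read a GAF 2.x annotation file
#'
#' Keeps columns DB_Object_ID (gene), Qualifier, GO_ID and Evidence.
#' Rows with a NOT qualifier or ND evidence are removed (the standard
#' filters for semantic-similarity and enrichment work); annotations to
#' terms missing from the ontology are dropped with a warning.
#'
#' @param path GAF file path (`!` comment lines ignored).
#' @param dag A [go_dag()].
#' @return An [annotation_set()].
#' @export
load_gaf <- function(path, dag) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "!", stringsAsFactors = FALSE)
  if (ncol(tab) < 7L) stop("GAF file needs >= 7 columns")
  gene <- as.character(tab[[2L]])
  qualifier <- as.character(tab[[4L]])
  go <- as.character(tab[[5L]])
  evidence <- as.character(tab[[7L]])
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier) & evidence != "ND"
  annotation_set(split(go[keep], gene[keep]), dag)
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' Every gene annotated to a term is counted at that term and at all of its
#' ancestors, so each namespace root carries every gene annotated in that
#' namespace.
#'
#' @param dag A [go_dag()].
#' @param ann An [annotation_set()].
#' @param namespace Optional: restrict to one namespace (`"BP"`, `"MF"`,
#'   `"CC"`).
#' @return Named list term id -> character vector of genes.
#' @export
propagate_annotations <- function(dag, ann, namespace = NULL) {
  stopifnot(inherits(dag, "GoDag"), inherits(ann, "AnnotationSet"))
  anc <- go_ancestors(dag)
  keep_ns <- function(ts) if (is.null(namespace)) ts else
    ts[dag$namespace[ts] == namespace]
  sets <- stats::setNames(lapply(dag$terms, function(t) character()), dag$terms)
  for (g in names(ann$annotations)) {
    direct <- keep_ns(intersect(ann$annotations[[g]], dag$terms))
    if (!length(direct)) next
    all_terms <- unique(c(direct, unlist(anc[direct])))
    all_terms <- keep_ns(all_terms)
    for (t in all_terms) sets[[t]] <- c(sets[[t]], g)
  }
  lapply(sets, unique)
}

#' Information content of GO terms
#'
#' IC(t) = -log(n_t / N) where n_t is the number of genes annotated to t
#' after true-path propagation and N is the number of genes with at least
#' one annotation in the namespace (the annotated corpus, not the whole
#' genome). Terms with no annotated gene get no IC entry. Natural-log
#' units by default; `base` is configurable.
#'
#' @param dag A [go_dag()].
#' @param ann An [annotation_set()].
#' @param namespace Namespace to compute within (default `"BP"`).
#' @param base Logarithm base (default `exp(1)`).
#' @return Named numeric vector term id -> IC; attribute `corpus_size` = N.
#' @export
ic_table <- function(dag, ann, namespace = "BP", base = exp(1)) {
  sets <- propagate_annotations(dag, ann, namespace = namespace)
  counts <- vapply(sets, length, 1L)
  genes <- unique(unlist(sets))
  n <- length(genes)
  if (n == 0L) stop("no annotated genes in namespace ", namespace)
  keep <- counts > 0L
  ic <- -log(counts[keep] / n) / log(base)
  attr(ic, "corpus_size") <- n
  ic
}

#' Resnik similarity between two GO terms
#'
#' The information content of the most informative common ancestor (MICA):
#' max IC over the common ancestors of the two terms (a term is an ancestor
#' of itself). Two terms whose only common ancestor is the namespace root
#' score 0.
#'
#' @param t1,t2 Term ids from the same namespace.
#' @param ic IC table from [ic_table()].
#' @param dag A [go_dag()].
#' @param ancestors Optional precomputed [go_ancestors()] list (saves
#'   recomputation in tight loops).
#' @return Non-negative similarity (0 when no informative common ancestor
#'   exists).
#' @export
resnik_term <- function(t1, t2, ic, dag, ancestors = NULL) {
  stopifnot(inherits(dag, "GoDag"))
  if (!t1 %in% dag$terms || !t2 %in% dag$terms)
    stop("unknown term id")
  if (dag$namespace[[t1]] != dag$namespace[[t2]])
    stop("no cross-namespace term similarity: ", t1, " is ",
         dag$namespace[[t1]], ", ", t2, " is ", dag$namespace[[t2]])
  if (is.null(ancestors)) ancestors <- go_ancestors(dag)
  common <- intersect(c(t1, ancestors[[t1]]), c(t2, ancestors[[t2]]))
  common <- common[common %in% names(ic)]
  if (!length(common)) return(0)
  max(ic[common])
}

#' Resnik similarity between two genes
#'
#' The maximum term-pair Resnik similarity over the two genes' direct
#' annotations in the namespace. Computed as the maximal IC over the
#' intersection of the genes' propagated term sets, which equals the
#' max-over-pairs definition.
#'
#' @param g1,g2 Gene ids.
#' @param ann An [annotation_set()].
#' @param ic IC table from [ic_table()].
#' @param dag A [go_dag()].
#' @param namespace Namespace (default `"BP"`).
#' @param ancestors Optional precomputed [go_ancestors()].
#' @return Non-negative similarity.
#' @export
goss_gene <- function(g1, g2, ann, ic, dag, namespace = "BP", ancestors = NULL) {
  stopifnot(inherits(ann, "AnnotationSet"))
  if (is.null(ancestors)) ancestors <- go_ancestors(dag)
  up <- function(g) {
    direct <- intersect(ann$annotations[[g]], dag$terms)
    direct <- direct[dag$namespace[direct] == namespace]
    if (!length(direct))
      stop("gene ", g, " has no ", namespace, " annotation")
    unique(c(direct, unlist(ancestors[direct])))
  }
  common <- intersect(up(g1), up(g2))
  common <- common[common %in% names(ic)]
  if (!length(common)) return(0)
  max(ic[common])
}

#' Gene-pair similarity context for TAPAS
#'
#' Bundles a memoised gene-pair Resnik scorer with the universe of genes
#' annotated in the namespace, so the clustering/filtering steps can share
#' one precomputed ancestor closure and cache.
#'
#' @param dag A [go_dag()].
#' @param ann An [annotation_set()].
#' @param namespace Namespace used throughout (default `"BP"`, the branch
#'   whose similarities are expected to track co-expression).
#' @param base IC logarithm base.
#' @return List with elements `score` (function(g1, g2) -> similarity, `NA`
#'   if either gene is unannotated), `annotated` (character vector),
#'   `ic`, `dag`, `ann`, `namespace`.
#' @export
goss_context <- function(dag, ann, namespace = "BP", base = exp(1)) {
  ic <- ic_table(dag, ann, namespace = namespace, base = base)
  ancestors <- go_ancestors(dag)
  annotated <- names(ann$annotations)[vapply(names(ann$annotations), function(g) {
    direct <- intersect(ann$annotations[[g]], dag$terms)
    any(dag$namespace[direct] == namespace)
  }, logical(1))]
  cache <- new.env(parent = emptyenv())
  score <- function(g1, g2) {
    if (!(g1 %in% annotated) || !(g2 %in% annotated)) return(NA_real_)
    key <- paste(sort(c(g1, g2)), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- goss_gene(g1, g2, ann, ic, dag, namespace = namespace,
                   ancestors = ancestors)
    cache[[key]] <- v
    v
  }
  list(score = score, annotated = annotated, ic = ic, dag = dag, ann = ann,
       namespace = namespace)
}
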