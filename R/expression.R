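#' Construct a time-course expression matrix
#'
#' Container for transcript-level FPKM values over an ordered series of
#' developmental stages, together with the transcript-to-gene mapping.
#' Stages are an ordered categorical axis (e.g. the modENCODE embryo to
#' adult series); no interpolation between stages is ever performed.
#'
#' @param expr Numeric matrix, transcripts in rows (rownames are transcript
#'   ids), stages in columns (colnames are stage labels, order preserved).
#'   All values must be finite and non-negative.
#' @param transcript_to_gene Named character vector mapping every row of
#'   `expr` to exactly one gene id.
#' @return An object of class `TimeCourseMatrix` with elements `expr`,
#'   `transcript_to_gene` and `stage_labels`.
#' @export
time_course_matrix <- function(expr, transcript_to_gene) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("'expr' needs transcript rownames and stage colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate transcript_id in expression matrix: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("FPKM values must be finite and non-negative")
  missing <- setdiff(rownames(expr), names(transcript_to_gene))
  if (length(missing))
    stop("transcripts missing from transcript_to_gene map: ",
         paste(missing, collapse = ", "))
  structure(
    list(expr = expr,
         transcript_to_gene = transcript_to_gene[rownames(expr)],
         stage_labels = colnames(expr)),
    class = "TimeCourseMatrix")
}

#' @export
print.TimeCourseMatrix <- function(x, ...) {
  cat("TimeCourseMatrix:", nrow(x$expr), "transcripts,",
      length(unique(x$transcript_to_gene)), "genes,",
      ncol(x$expr), "stages\n")
  cat("stages:", paste(utils::head(x$stage_labels, 5), collapse = ", "),
      if (ncol(x$expr) > 5) "..." else "", "\n")
  invisible(x)
}

#' Read a transcript expression table
#'
#' Reads a tab-separated table with columns `transcript_id`, `gene_id` and
#' one numeric FPKM column per developmental stage (stage order is taken
#' from the header). Rows carrying a negative FPKM are excluded with a
#' warning; duplicated transcript ids are an error.
#'
#' @param path Path to the TSV file.
#' @return A [time_course_matrix()] object.
#' @export
load_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || names(tab)[1] != "transcript_id" || names(tab)[2] != "gene_id")
    stop("expression table must start with 'transcript_id' and 'gene_id' columns")
  if (anyDuplicated(tab$transcript_id))
    stop("duplicate transcript_id in ", path, ": ",
         paste(unique(tab$transcript_id[duplicated(tab$transcript_id)]), collapse = ", "))
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  bad <- apply(vals, 1L, function(v) any(!is.finite(v)) || any(v < 0))
  if (any(bad)) {
    warning("excluding ", sum(bad), " row(s) with negative or non-numeric FPKM: ",
            paste(tab$transcript_id[bad], collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
    vals <- vals[!bad, , drop = FALSE]
  }
  rownames(vals) <- tab$transcript_id
  map <- stats::setNames(tab$gene_id, tab$transcript_id)
  time_course_matrix(vals, map)
}

#' Read a transcript-to-protein mapping
#'
#' Protein identity is exact string equality of the supplied protein
#' sequences (or keys): two transcripts encode the "same protein" iff their
#' values are identical strings. Accepts either a protein FASTA keyed by
#' transcript id (sequence text becomes the protein key) or a two-column
#' TSV `transcript_id<TAB>protein_key`.
#'
#' @param path FASTA (`.fa`, `.fasta`, `.faa`, or any file whose first
#'   non-empty character is `>`) or two-column TSV.
#' @return Named character vector: transcript id -> protein key.
#' @export
read_protein_map <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE) ||
      (length(first) && startsWith(trimws(first), ">"))) {
    aa <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
    return(stats::setNames(as.character(aa), ids))
  }
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "transcript_id"))
    tab <- tab[-1, , drop = FALSE]
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Construct a gene isoform set
#'
#' Holds one gene's transcripts with their protein key and mean expression,
#' sorted by decreasing mean expression (ties broken lexicographically by
#' transcript id, so ordering is deterministic). Primary/secondary/minor
#' designation is filled in by [designate_isoforms()].
#'
#' @param gene_id Gene identifier.
#' @param transcript_id,protein_key,mean_expression Parallel vectors
#'   describing the transcripts.
#' @return An object of class `GeneIsoformSet`.
#' @export
gene_isoform_set <- function(gene_id, transcript_id, protein_key, mean_expression) {
  tr <- data.frame(transcript_id = as.character(transcript_id),
                   protein_key = as.character(protein_key),
                   mean_expression = as.numeric(mean_expression),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(tr$transcript_id))
    stop("duplicate transcript ids for gene ", gene_id)
  tr <- tr[order(-tr$mean_expression, tr$transcript_id), , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(gene_id = gene_id, transcripts = tr,
                 primary_id = NULL, secondary_id = NULL, minor_ids = NULL),
            class = "GeneIsoformSet")
}

#' @export
print.GeneIsoformSet <- function(x, ...) {
  cat("GeneIsoformSet", x$gene_id, "-", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$protein_key)), "distinct proteins\n")
  if (!is.null(x$primary_id))
    cat("  primary:", x$primary_id,
        " secondary:", x$secondary_id %||% "<none>",
        " minors:", paste(x$minor_ids, collapse = ", "), "\n")
  print(x$transcripts)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict an expression matrix to multi-protein genes
#'
#' Applies the expression filter (a transcript is retained only if its FPKM
#' exceeds `min_fpkm` in at least one stage; the inequality is strict) and
#' keeps only genes whose surviving transcripts encode at least two distinct
#' protein sequences. Mean expression is the unweighted arithmetic mean of a
#' transcript's full FPKM vector over all stages.
#'
#' @param m A [time_course_matrix()] object.
#' @param proteins Named character vector transcript id -> protein key (see
#'   [read_protein_map()]). Every retained transcript must be present.
#' @param min_fpkm Expression threshold; default 1 FPKM.
#' @return A list of designated [gene_isoform_set()] objects (one per
#'   multi-protein gene), named by gene id.
#' @export
filter_multiprotein_genes <- function(m, proteins, min_fpkm = 1.0) {
  stopifnot(inherits(m, "TimeCourseMatrix"))
  keep <- apply(m$expr, 1L, max) > min_fpkm
  tids <- rownames(m$expr)[keep]
  if (!length(tids)) return(list())
  missing <- setdiff(tids, names(proteins))
  if (length(missing))
    stop("transcript(s) missing from protein map: ", paste(missing, collapse = ", "))
  means <- rowMeans(m$expr[tids, , drop = FALSE])
  genes <- m$transcript_to_gene[tids]
  out <- list()
  for (g in sort(unique(genes))) {
    gt <- tids[genes == g]
    if (length(unique(proteins[gt])) < 2L) next
    out[[g]] <- designate_isoforms(
      gene_isoform_set(g, gt, proteins[gt], means[gt]))
  }
  out
}

#' Designate primary, secondary and minor isoforms
#'
#' The primary isoform is the transcript with the maximum mean expression
#' (ties broken lexicographically by transcript id). The secondary isoform
#' is the highest-mean transcript whose protein key differs from the
#' primary's; the minor set is every transcript whose protein differs from
#' the primary's. Idempotent.
#'
#' @param g A [gene_isoform_set()] with at least two transcripts carrying at
#'   least two distinct protein keys.
#' @return `g` with `primary_id`, `secondary_id` and `minor_ids` filled in.
#' @export
designate_isoforms <- function(g) {
  stopifnot(inherits(g, "GeneIsoformSet"))
  tr <- g$transcripts
  if (nrow(tr) < 2L || length(unique(tr$protein_key)) < 2L)
    stop("gene ", g$gene_id,
         ": need >= 2 transcripts with >= 2 distinct protein keys")
  g$primary_id <- tr$transcript_id[1L]
  prim_prot <- tr$protein_key[1L]
  minor <- tr$transcript_id[tr$protein_key != prim_prot]
  g$minor_ids <- minor
  g$secondary_id <- minor[1L]
  g
}
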