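#' Write an expression matrix as the TSV the loaders read
#'
#' Header `transcript_id<TAB>gene_id<TAB><stage1>...`; one row per
#' transcript.
#'
#' @param m A [time_course_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "TimeCourseMatrix"))
  tab <- data.frame(transcript_id = rownames(m$expr),
                    gene_id = unname(m$transcript_to_gene),
                    m$expr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write transcript models as GTF
#'
#' One `exon` feature line per exon, FlyBase-style attributes
#' `gene_id "..."; transcript_id "...";`, 1-based inclusive coordinates.
#'
#' @param models List of [transcript_model()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(t) {
    sprintf('%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            t$seqname, t$exons[, "start"], t$exons[, "end"], t$strand,
            t$gene_id, t$transcript_id)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a GO DAG as OBO 1.2
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "GoDag"))
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", t),
                 paste0("namespace: ", ns_long[[dag$namespace[[t]]]]),
                 paste0("is_a: ", dag$parents[[t]]),
                 ""), con)
  }
  invisible(path)
}

#' Write an annotation set as GAF 2.2
#'
#' @param ann An [annotation_set()].
#' @param dag The [go_dag()] the annotations refer to (for the aspect
#'   column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, dag, path) {
  stopifnot(inherits(ann, "AnnotationSet"), inherits(dag, "GoDag"))
  aspect <- c(BP = "P", MF = "F", CC = "C")
  rows <- character()
  for (g in names(ann$annotations)) {
    for (t in ann$annotations[[g]]) {
      rows <- c(rows, paste(
        "SIM", g, g, "", t, "SIM_REF:0000001", "IEA", "",
        aspect[[dag$namespace[[t]]]], g, "", "protein", "taxon:7227",
        "20260101", "SIM", "", "", sep = "\t"))
    }
  }
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Write an interaction network as edge-list TSVs
#'
#' Experimental edges go to `<prefix>_ppi.tsv` (`geneA<TAB>geneB`), STRING
#' edges to `<prefix>_string.tsv` (`geneA<TAB>geneB<TAB>score`).
#'
#' @param net An [interaction_network()].
#' @param prefix Output path prefix.
#' @return Character vector of the paths written, invisibly.
#' @export
write_network_tsv <- function(net, prefix) {
  stopifnot(inherits(net, "InteractionNetwork"))
  paths <- character()
  split_keys <- function(k) do.call(rbind, strsplit(k, "\r", fixed = TRUE))
  if (length(net$experimental)) {
    p <- paste0(prefix, "_ppi.tsv")
    utils::write.table(split_keys(net$experimental), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(net$string)) {
    p <- paste0(prefix, "_string.tsv")
    utils::write.table(cbind(split_keys(names(net$string)), unname(net$string)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read interaction edge lists
#'
#' @param ppi Path to a `geneA<TAB>geneB` experimental edge list, or `NULL`.
#' @param string Path to a `geneA<TAB>geneB<TAB>score` STRING-style edge
#'   list, or `NULL`.
#' @return An [interaction_network()].
#' @export
load_network <- function(ppi = NULL, string = NULL) {
  interaction_network(
    experimental = if (!is.null(ppi))
      utils::read.delim(ppi, header = FALSE, stringsAsFactors = FALSE),
    string = if (!is.null(string))
      utils::read.delim(string, header = FALSE, stringsAsFactors = FALSE))
}

#' Read an exon conservation-index table
#'
#' TSV `seqname<TAB>start<TAB>end<TAB>ci`.
#'
#' @param path TSV path.
#' @return `data.frame` with those columns.
#' @export
load_conservation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "seqname")) tab <- tab[-1, , drop = FALSE]
  data.frame(seqname = as.character(tab[[1]]), start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]), ci = as.numeric(tab[[4]]),
             stringsAsFactors = FALSE)
}
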