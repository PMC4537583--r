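#' Construct a transcript model
#'
#' Exon coordinates are 1-based inclusive genomic intervals, as in GTF;
#' they are kept that way internally (no half-open conversion anywhere).
#'
#' @param transcript_id,gene_id,seqname Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of (start, end), 1-based
#'   inclusive. Exons are sorted; they must be pairwise disjoint and each
#'   must satisfy start <= end.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, seqname, strand, exons) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] < exons[, "start"]))
    stop("transcript ", transcript_id, ": exon with end < start")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"]))
    stop("transcript ", transcript_id, ": overlapping exons")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 seqname = seqname, strand = strand, exons = exons),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat("TranscriptModel", x$transcript_id, "(", x$gene_id, ")",
      x$seqname, x$strand, "-", nrow(x$exons), "exons,",
      x$exons[1, "start"], "-", x$exons[nrow(x$exons), "end"], "\n")
  invisible(x)
}

#' Read transcript models from a GTF file
#'
#' Exon features are grouped per transcript via their `gene_id` and
#' `transcript_id` attributes (FlyBase-style GTF). Coordinates stay 1-based
#' inclusive. An exon record without a transcript_id attribute is a hard
#' error reporting the offending line number(s).
#'
#' @param path GTF file path.
#' @return Named list of [transcript_model()] objects.
#' @export
load_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    raw <- readLines(path)
    bad <- which(grepl("\texon\t", raw) & !grepl("transcript_id", raw))
    stop("exon feature(s) missing transcript_id attribute in ", path,
         if (length(bad)) paste0(" (line ", paste(bad, collapse = ", "), ")"))
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon feature(s) missing gene_id attribute in ", path)
  idx <- split(seq_along(gr), gr$transcript_id)
  models <- lapply(names(idx), function(tid) {
    sub <- gr[idx[[tid]]]
    gid <- unique(sub$gene_id)
    sq <- unique(as.character(GenomicRanges::seqnames(sub)))
    st <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(gid) != 1L || length(sq) != 1L || length(st) != 1L)
      stop("transcript ", tid, ": inconsistent gene_id/seqname/strand")
    transcript_model(tid, gid, sq, if (st == "*") "+" else st,
                     cbind(GenomicRanges::start(sub), GenomicRanges::end(sub)))
  })
  stats::setNames(models, names(idx))
}

#' Introns of a transcript model
#'
#' For consecutive exons (a1, a2), (b1, b2) the intron is (a2 + 1, b1 - 1),
#' 1-based inclusive. Single-exon transcripts have none.
#'
#' @param t A [transcript_model()].
#' @return Integer matrix with columns `start`, `end` (0 rows if none).
#' @export
introns <- function(t) {
  stopifnot(inherits(t, "TranscriptModel"))
  ex <- t$exons
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-n, "end"] + 1L, end = ex[-1L, "start"] - 1L)
}

#' Classify splicing events between a primary and a minor isoform
#'
#' Two event kinds are detected, following the coordinate rules used for
#' primary/minor comparisons of FlyBase-style models:
#' * **exon_gain** - a minor-isoform exon sharing no base with any exon of
#'   the primary isoform (the reported interval is the gained exon);
#' * **intron_retention** - a minor-isoform exon whose interval fully
#'   contains an intron of the primary isoform (the reported interval is
#'   the retained intron; one minor exon can retain several introns).
#'
#' Overlap means >= 1 shared base on the same seqname. Exon *loss* is the
#' same classification with the arguments swapped.
#'
#' @param primary,minor [transcript_model()] objects from the same gene
#'   (same gene_id, seqname and strand; anything else is an error).
#' @return A `data.frame` with columns `kind`, `gene_id`, `primary_id`,
#'   `minor_id`, `start`, `end`, `conserved` (logical, `NA` until
#'   [flag_conserved()] is applied); zero rows when no event is found.
#' @export
classify_events <- function(primary, minor) {
  stopifnot(inherits(primary, "TranscriptModel"), inherits(minor, "TranscriptModel"))
  if (!identical(primary$gene_id, minor$gene_id))
    stop("isoforms from different genes: ", primary$gene_id, " vs ", minor$gene_id)
  if (!identical(primary$seqname, minor$seqname))
    stop("isoforms on different seqnames")
  if (!identical(primary$strand, minor$strand))
    stop("isoforms on different strands")
  pex <- IRanges::IRanges(primary$exons[, "start"], primary$exons[, "end"])
  mex <- IRanges::IRanges(minor$exons[, "start"], minor$exons[, "end"])
  ev <- list()
  gained <- !IRanges::overlapsAny(mex, pex)
  if (any(gained))
    ev[[1L]] <- data.frame(kind = "exon_gain",
                           start = minor$exons[gained, "start"],
                           end = minor$exons[gained, "end"])
  pint <- introns(primary)
  if (nrow(pint)) {
    pir <- IRanges::IRanges(pint[, "start"], pint[, "end"])
    hits <- IRanges::findOverlaps(pir, mex, type = "within")
    if (length(hits)) {
      i <- S4Vectors::queryHits(hits)
      ev[[length(ev) + 1L]] <- data.frame(kind = "intron_retention",
                                          start = pint[i, "start"],
                                          end = pint[i, "end"])
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(), start = integer(), end = integer())
  data.frame(kind = out$kind, gene_id = rep(primary$gene_id, nrow(out)),
             primary_id = rep(primary$transcript_id, nrow(out)),
             minor_id = rep(minor$transcript_id, nrow(out)),
             start = out$start, end = out$end,
             conserved = rep(NA, nrow(out)),
             stringsAsFactors = FALSE)
}

#' Flag events overlapping evolutionarily conserved exons
#'
#' Matches each event interval against a table of exon conservation-index
#' (CI) records. An exact (seqname, start, end) match is preferred; failing
#' that, the overlapping record with maximal overlap is used (annotation
#' versions can shift exon coordinates by a few bases). An event with no
#' matching record keeps `conserved = NA` - unknown, not FALSE.
#'
#' @param events Event table from [classify_events()], plus a `seqname`
#'   column if the events span several sequences (otherwise supply
#'   `seqname`).
#' @param cons `data.frame` with columns `seqname`, `start`, `end`, `ci`.
#' @param cutoff CI value at or above which an exon counts as conserved
#'   (default 5, the value separating the conserved from the unconserved
#'   mode of the modENCODE CI score distribution). Comparison is `>=`.
#' @param seqname Seqname applied to every event when `events` lacks a
#'   `seqname` column.
#' @return `events` with the `conserved` column filled where a record
#'   matched.
#' @export
flag_conserved <- function(events, cons, cutoff = 5.0, seqname = NULL) {
  if (!nrow(events)) return(events)
  sq <- if ("seqname" %in% names(events)) events$seqname else
    rep(seqname %||% stop("supply 'seqname' or a seqname column"), nrow(events))
  for (i in seq_len(nrow(events))) {
    rec <- cons[cons$seqname == sq[i], , drop = FALSE]
    if (!nrow(rec)) next
    exact <- rec$start == events$start[i] & rec$end == events$end[i]
    if (any(exact)) {
      events$conserved[i] <- rec$ci[which(exact)[1L]] >= cutoff
      next
    }
    ov <- pmin(rec$end, events$end[i]) - pmax(rec$start, events$start[i]) + 1L
    if (any(ov > 0L))
      events$conserved[i] <- rec$ci[which.max(ov)] >= cutoff
  }
  events
}

#' Classify events for every designated gene
#'
#' Convenience driver: runs [classify_events()] for each (primary, minor)
#' pair of each gene. With `symmetric = TRUE` the swapped comparison is run
#' as well, so exons lost in the minor isoform are reported too (as gains
#' of the primary relative to the minor).
#'
#' @param genes List of designated [gene_isoform_set()] objects.
#' @param models Named list of [transcript_model()]s (e.g. from
#'   [load_gtf()]).
#' @param symmetric Also classify with primary and minor swapped.
#' @return Combined event `data.frame`; genes or transcripts without models
#'   are skipped with a warning.
#' @export
events_for_genes <- function(genes, models, symmetric = FALSE) {
  rows <- list(); skipped <- character()
  for (g in genes) {
    if (is.null(g$primary_id)) g <- designate_isoforms(g)
    ids <- c(g$primary_id, g$minor_ids)
    if (!all(ids %in% names(models))) { skipped <- c(skipped, g$gene_id); next }
    for (mid in g$minor_ids) {
      rows[[length(rows) + 1L]] <- classify_events(models[[g$primary_id]], models[[mid]])
      if (symmetric)
        rows[[length(rows) + 1L]] <- classify_events(models[[mid]], models[[g$primary_id]])
    }
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " gene(s) without transcript models")
  if (length(rows)) do.call(rbind, rows) else
    classify_events_empty()
}

classify_events_empty <- function() {
  data.frame(kind = character(), gene_id = character(), primary_id = character(),
             minor_id = character(), start = integer(), end = integer(),
             conserved = logical(), stringsAsFactors = FALSE)
}
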