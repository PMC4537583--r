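#' Time-course Switch (TS) score between two expression profiles
#'
#' The TS score measures how strongly a minor isoform's expression profile
#' diverges from the primary isoform's, counting shape and magnitude
#' differences equally. Stack the two FPKM vectors as the rows of a 2 x T
#' matrix X and take its singular values s1 >= s2 >= 0; the score is
#'
#'   TS = 2 * (1 - s1 / (s1 + s2))
#'
#' which is 0 when the profiles are proportional (rank-1 X) and 1 when they
#' are orthogonal with equal norms. The score is symmetric in its arguments
#' and invariant to scaling both profiles by the same positive constant; it
#' increases as the shapes diverge at fixed norms and as the norms balance
#' at a fixed angle.
#'
#' Profiles enter as raw FPKM vectors by default: the score's sensitivity
#' to relative magnitude is the point, and a log transform would suppress
#' it. `log1p = TRUE` applies `log1p()` to both vectors first for users who
#' want a variance-stabilised variant.
#'
#' @param p,q Non-negative numeric vectors of equal length >= 2, each with
#'   at least one positive entry.
#' @param log1p Apply `log1p()` to both profiles before scoring.
#' @return TS score in \[0, 1\].
#' @examples
#' ts_score(c(1, 2, 3), c(2, 4, 6))  # proportional -> 0
#' ts_score(c(1, 0), c(0, 1))        # orthogonal, equal norm -> 1
#' ts_score(c(2, 0), c(0, 1))        # singular values 2 and 1 -> 2/3
#' @export
ts_score <- function(p, q, log1p = FALSE) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q) || length(p) < 2L)
    stop("profiles must have equal length >= 2")
  if (any(!is.finite(p)) || any(!is.finite(q)) || any(p < 0) || any(q < 0))
    stop("profiles must be finite and non-negative")
  if (all(p == 0) && all(q == 0))
    stop("TS score undefined: both profiles are all-zero (0/0)")
  if (all(p == 0) || all(q == 0))
    stop("TS score requires each profile to have at least one positive entry")
  if (log1p) { p <- base::log1p(p); q <- base::log1p(q) }
  s <- svd(rbind(p, q), nu = 0L, nv = 0L)$d
  2 * (1 - s[1L] / sum(s))
}

#' TS scores for designated genes
#'
#' Scores the primary isoform of each gene against its minor isoforms.
#' By default only the primary-secondary pair is reported (the gene-level
#' score used for high-TS designation); `pairs = "all"` scores every
#' primary-minor pair. A gene is flagged high-TS when its score strictly
#' exceeds `threshold`.
#'
#' @param genes List of designated [gene_isoform_set()] objects.
#' @param m A [time_course_matrix()] holding the profiles.
#' @param threshold High-TS threshold (strict `>`); default 0.5.
#' @param pairs `"secondary"` (default) or `"all"`.
#' @param log1p Passed to [ts_score()].
#' @return `data.frame` with columns `gene_id`, `minor_transcript_id`, `ts`,
#'   `is_high_ts`. Genes with profiles missing from `m` are skipped with a
#'   warning.
#' @export
ts_scores_for_genes <- function(genes, m, threshold = 0.5,
                                pairs = c("secondary", "all"), log1p = FALSE) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(m, "TimeCourseMatrix"))
  rows <- list()
  skipped <- character()
  for (g in genes) {
    if (is.null(g$primary_id)) g <- designate_isoforms(g)
    minors <- if (pairs == "secondary") g$secondary_id else g$minor_ids
    need <- c(g$primary_id, minors)
    if (!all(need %in% rownames(m$expr))) {
      skipped <- c(skipped, g$gene_id)
      next
    }
    pp <- m$expr[g$primary_id, ]
    for (mid in minors) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, minor_transcript_id = mid,
        ts = ts_score(pp, m$expr[mid, ], log1p = log1p),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " gene(s) with missing profiles: ",
            paste(skipped, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), minor_transcript_id = character(),
               ts = numeric(), stringsAsFactors = FALSE)
  out$is_high_ts <- out$ts > threshold
  out
}

#' Pearson dissimilarity between two profiles
#'
#' `1 - cor(p, q)`, in \[0, 2\]. Shape-only reference measure: unlike the TS
#' score it ignores relative magnitude, so a flat, lowly expressed minor
#' isoform can still look maximally "dissimilar".
#'
#' @param p,q Numeric vectors of equal length >= 2, each non-constant.
#' @return Dissimilarity in \[0, 2\].
#' @export
pearson_dissimilarity <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q) || length(p) < 2L)
    stop("profiles must have equal length >= 2")
  if (stats::sd(p) == 0 || stats::sd(q) == 0)
    stop("Pearson dissimilarity undefined for constant profiles")
  1 - stats::cor(p, q)
}

#' Euclidean distance between two profiles
#'
#' Magnitude-dominated reference measure for comparison against the TS
#' score.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("profiles must have equal length")
  sqrt(sum((p - q)^2))
}
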