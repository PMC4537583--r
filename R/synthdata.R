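#' Simulation configuration for expression fixtures
#'
#' Defaults emulate the shape of a staged developmental RNA-seq series:
#' 30 ordered stages (embryonic 2-h windows, larval, white prepupa, pupal
#' and adult samples), smooth single-bump primary profiles, and three minor
#' isoform archetypes:
#' * `switch` - bump at a well-separated centre with magnitude comparable
#'   to the primary (ratio 0.3-1.0): the planted high-TS case;
#' * `replica` - scalar multiple of the primary profile (ratio 0.05-0.5):
#'   planted TS ~ 0;
#' * `noise` - flat, lowly expressed profile (0.5-2 FPKM): planted low TS.
#'
#' Noise is multiplicative log-normal on every FPKM value (non-negativity
#' preserved, magnitude-proportional scatter).
#'
#' @param n_genes Number of multi-protein genes.
#' @param n_stages Number of developmental stages (30 by default).
#' @param minor_per_gene Possible numbers of minor isoforms per gene
#'   (sampled uniformly).
#' @param archetype_probs Named probabilities for `switch`, `replica`,
#'   `noise`; must sum to 1.
#' @param peak_range Primary bump peak height range (FPKM), sampled
#'   log-uniformly.
#' @param width_range Bump width range (stages).
#' @param switch_ratio Range of minor/primary peak ratio for `switch`.
#' @param replica_ratio Range of scalar for `replica`.
#' @param noise_level Range of the flat `noise` archetype level (FPKM).
#' @param noise_sigma Log-normal sigma of the multiplicative noise.
#' @param seed RNG seed (mandatory: every simulation is reproducible).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100, n_stages = 30, minor_per_gene = 1:2,
                       archetype_probs = c(switch = 0.2, replica = 0.4, noise = 0.4),
                       peak_range = c(20, 200), width_range = c(2, 5),
                       switch_ratio = c(0.3, 1.0), replica_ratio = c(0.05, 0.5),
                       noise_level = c(0.5, 2), noise_sigma = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic simulation")
  stopifnot(abs(sum(archetype_probs) - 1) < 1e-8,
            all(archetype_probs >= 0), n_stages >= 4)
  structure(list(n_genes = n_genes, n_stages = n_stages,
                 minor_per_gene = minor_per_gene,
                 archetype_probs = archetype_probs, peak_range = peak_range,
                 width_range = width_range, switch_ratio = switch_ratio,
                 replica_ratio = replica_ratio, noise_level = noise_level,
                 noise_sigma = noise_sigma, seed = seed),
            class = "sim_config")
}

#' modENCODE-style stage labels
#'
#' 30 labels spanning twelve 2-h embryonic windows, six larval samples,
#' white prepupae, six pupal samples and five adult (female/male) samples;
#' generic `S1..Sn` labels for any other length.
#'
#' @param n Number of stages.
#' @return Character vector of length `n`.
#' @export
stage_labels <- function(n = 30) {
  if (n != 30) return(paste0("S", seq_len(n)))
  c(sprintf("E%02dh", seq(2, 24, by = 2)),
    "L1", "L2", "L3_12h", "L3_PS1", "L3_PS3", "L3_PS6",
    "WPP", "P5", "P6", "P8", "P9", "P10",
    "AdF1d", "AdM1d", "AdF5d", "AdM5d", "AdF30d", "AdM30d")
}

bump_profile <- function(n_stages, centre, width, peak, baseline = 0.05) {
  t <- seq_len(n_stages)
  baseline + peak * exp(-(t - centre)^2 / (2 * width^2))
}

apply_lognormal_noise <- function(x, sigma) {
  if (sigma == 0) return(x)
  x * stats::rlnorm(length(x), meanlog = 0, sdlog = sigma)
}

#' Simulate a transcript expression time course with planted switches
#'
#' Each gene gets a primary isoform with a smooth bump profile and one or
#' more minor isoforms drawn from the three archetypes of [sim_config()].
#' Switch minors are placed at a centre at least `2 * (w1 + w2)` stages
#' away from the primary's, so the shapes barely overlap. Every isoform
#' gets its own protein key (so every simulated gene is a multi-protein
#' gene); bit-identical output for the same seed.
#'
#' @param cfg A [sim_config()].
#' @return List: `matrix` ([time_course_matrix()]), `truth` (`data.frame`
#'   gene_id, transcript_id, role = primary/minor, archetype), `proteins`
#'   (named character vector for [filter_multiprotein_genes()]).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_stages
  rows <- list(); truth <- list(); proteins <- character()
  runif_in <- function(r) stats::runif(1, r[1], r[2])
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", i)
    w1 <- runif_in(cfg$width_range)
    c1 <- stats::runif(1, 1 + w1, n - w1)
    peak <- exp(stats::runif(1, log(cfg$peak_range[1]), log(cfg$peak_range[2])))
    primary <- bump_profile(n, c1, w1, peak)
    ptid <- paste0("T", gid, ".1")
    rows[[ptid]] <- apply_lognormal_noise(primary, cfg$noise_sigma)
    proteins[ptid] <- paste0("P", gid, ".a")
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = gid, transcript_id = ptid, role = "primary",
      archetype = NA_character_, stringsAsFactors = FALSE)
    n_minor <- if (length(cfg$minor_per_gene) == 1L) cfg$minor_per_gene else
      sample(cfg$minor_per_gene, 1L)
    for (j in seq_len(n_minor)) {
      arch <- sample(names(cfg$archetype_probs), 1L, prob = cfg$archetype_probs)
      tid <- paste0("T", gid, ".", j + 1L)
      prof <- switch(arch,
        switch = {
          w2 <- runif_in(cfg$width_range)
          gap <- 2 * (w1 + w2)
          lo_left <- 1 + w2; hi_left <- c1 - gap
          lo_right <- c1 + gap; hi_right <- n - w2
          left_len <- max(0, hi_left - lo_left)
          right_len <- max(0, hi_right - lo_right)
          if (left_len + right_len <= 0) {
            # no room for a separated bump: push to the far boundary
            c2 <- if (c1 > n / 2) 1 else n
          } else {
            u <- stats::runif(1, 0, left_len + right_len)
            c2 <- if (u < left_len) lo_left + u else lo_right + (u - left_len)
          }
          bump_profile(n, c2, w2, peak * runif_in(cfg$switch_ratio))
        },
        replica = primary * runif_in(cfg$replica_ratio),
        noise = rep(runif_in(cfg$noise_level), n))
      rows[[tid]] <- apply_lognormal_noise(prof, cfg$noise_sigma)
      proteins[tid] <- paste0("P", gid, ".", letters[j + 1L])
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, role = "minor",
        archetype = arch, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  expr <- do.call(rbind, rows)
  colnames(expr) <- stage_labels(n)
  map <- stats::setNames(truth$gene_id, truth$transcript_id)
  list(matrix = time_course_matrix(expr, map), truth = truth,
       proteins = proteins)
}

#' Simulate transcript models with planted splicing events
#'
#' For each gene, a multi-exon primary model is generated, then a minor
#' isoform is derived by one of:
#' * `gain` - insert an extra exon strictly inside an intron (or upstream
#'   of the first exon), overlapping nothing: planted exon gain;
#' * `ir` - merge two adjacent exons across their intron: planted intron
#'   retention of exactly that intron;
#' * `none` - boundary-shift decoy: one exon extended into its intron by a
#'   few bases without fully covering it, which must yield no event.
#'
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @param kinds Event kinds to sample from (uniformly).
#' @return List: `models` (named list of [transcript_model()]s, two per
#'   gene), `truth` (`data.frame` gene_id, primary_id, minor_id, kind,
#'   start, end; `kind = "none"` rows have `NA` coordinates).
#' @export
simulate_gene_models <- function(n_genes = 100, seed,
                                 kinds = c("gain", "ir", "none")) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic simulation")
  set.seed(seed)
  chroms <- c("2L", "2R", "3L", "3R", "X")
  models <- list(); truth <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("G%04d", i)
    n_ex <- sample(3:8, 1L)
    ex_len <- sample(50:300, n_ex, replace = TRUE)
    in_len <- sample(80:500, n_ex - 1L, replace = TRUE)
    start <- (i - 1L) * 10000L + sample(1:100, 1L)
    starts <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
    exons <- cbind(start = starts, end = starts + ex_len - 1L)
    sq <- sample(chroms, 1L)
    strand <- sample(c("+", "-"), 1L)
    pid <- paste0("T", gid, ".1"); mid <- paste0("T", gid, ".2")
    models[[pid]] <- transcript_model(pid, gid, sq, strand, exons)
    kind <- sample(kinds, 1L)
    mexons <- exons
    if (kind == "gain") {
      k <- sample(n_ex - 1L, 1L)  # host intron
      istart <- exons[k, "end"] + 1L; iend <- exons[k + 1L, "start"] - 1L
      ilen <- iend - istart + 1L
      glen <- sample(20:min(60, ilen - 4L), 1L)
      gstart <- istart + sample.int(ilen - glen - 1L, 1L)  # >= 1 bp margin
      mexons <- rbind(mexons, c(gstart, gstart + glen - 1L))
      ev <- c(gstart, gstart + glen - 1L)
    } else if (kind == "ir") {
      k <- sample(n_ex - 1L, 1L)
      ev <- c(exons[k, "end"] + 1L, exons[k + 1L, "start"] - 1L)
      mexons[k, "end"] <- mexons[k + 1L, "end"]
      mexons <- mexons[-(k + 1L), , drop = FALSE]
    } else {
      k <- sample(n_ex - 1L, 1L)
      ilen <- exons[k + 1L, "start"] - exons[k, "end"] - 1L
      d <- sample(5:min(20, ilen - 1L), 1L)
      mexons[k, "end"] <- mexons[k, "end"] + d
      ev <- c(NA_integer_, NA_integer_)
    }
    models[[mid]] <- transcript_model(mid, gid, sq, strand, mexons)
    truth[[i]] <- data.frame(gene_id = gid, primary_id = pid, minor_id = mid,
                             kind = kind, start = ev[1L], end = ev[2L],
                             stringsAsFactors = FALSE)
  }
  list(models = models, truth = do.call(rbind, truth))
}

#' Simulate a GO DAG with planted functional modules
#'
#' Builds a biological-process ontology rooted at one term, with one branch
#' per module ending in a specific leaf term, and annotates each module's
#' genes to its leaf. All remaining corpus genes are annotated directly to
#' the root, so unrelated gene pairs score 0 and within-module pairs score
#' IC(leaf) = -ln(module size / corpus size) exactly.
#'
#' @param n_modules Number of planted modules.
#' @param module_genes Named list module -> gene ids, or an integer module
#'   size (genes are then auto-named `M<i>_G<j>`).
#' @param background_genes Character vector of root-only genes (or an
#'   integer count, auto-named `BG_G<j>`).
#' @param seed RNG seed (annotation order shuffling only; structure is
#'   deterministic).
#' @return List: `dag`, `ann`, `truth` (`data.frame` gene, module;
#'   background genes have `module = NA`), `module_terms` (named character
#'   vector).
#' @export
simulate_go <- function(n_modules = 5, module_genes = 5, background_genes = 70,
                        seed = 1) {
  set.seed(seed)
  if (is.numeric(module_genes))
    module_genes <- lapply(stats::setNames(seq_len(n_modules),
                                           paste0("M", seq_len(n_modules))),
                           function(i) sprintf("M%d_G%02d", i, seq_len(module_genes)))
  stopifnot(length(module_genes) == n_modules)
  if (is.null(names(module_genes)))
    names(module_genes) <- paste0("M", seq_len(n_modules))
  if (is.numeric(background_genes))
    background_genes <- sprintf("BG_G%03d", seq_len(background_genes))
  root <- "GO:0000001"
  branch <- sprintf("GO:00001%02d", seq_len(n_modules))
  leaf <- sprintf("GO:00002%02d", seq_len(n_modules))
  terms <- c(root, branch, leaf)
  parents <- c(stats::setNames(list(character()), root),
               stats::setNames(lapply(branch, function(b) root), branch),
               stats::setNames(lapply(seq_len(n_modules), function(i) branch[i]), leaf))
  dag <- go_dag(terms, parents, stats::setNames(rep("BP", length(terms)), terms))
  ann <- c(lapply(stats::setNames(unlist(module_genes), unlist(module_genes)),
                  function(g) character()),
           lapply(stats::setNames(background_genes, background_genes),
                  function(g) root))
  for (i in seq_len(n_modules))
    for (g in module_genes[[i]]) ann[[g]] <- leaf[i]
  truth <- data.frame(
    gene = c(unlist(module_genes, use.names = FALSE), background_genes),
    module = c(rep(names(module_genes),
                   vapply(module_genes, length, 1L)),
               rep(NA_character_, length(background_genes))),
    stringsAsFactors = FALSE)
  list(dag = dag, ann = annotation_set(ann, dag), truth = truth,
       module_terms = stats::setNames(leaf, names(module_genes)))
}

#' Simulate an interaction network around planted modules
#'
#' Plants experimental and STRING edges between a hub gene and (or among)
#' the genes of each module, plus optional random background edges between
#' unrelated genes.
#'
#' @param modules Named list module -> gene ids; edges are planted among
#'   all within-module pairs with probability `module_edge_density`.
#' @param edge_type `"experimental"` or `"string"` per module (recycled).
#' @param all_genes Gene universe for background edges.
#' @param module_edge_density Probability of each within-module edge.
#' @param background_density Probability of each cross-module edge.
#' @param string_score_range Score range for planted STRING edges.
#' @param background_score_range Score range for background STRING edges.
#' @param seed RNG seed.
#' @return An [interaction_network()].
#' @export
simulate_network <- function(modules, edge_type = "experimental",
                             all_genes = unique(unlist(modules)),
                             module_edge_density = 1, background_density = 0,
                             string_score_range = c(850, 999),
                             background_score_range = c(150, 700), seed = 1) {
  set.seed(seed)
  edge_type <- rep_len(edge_type, length(modules))
  exp_edges <- list(); str_edges <- list()
  for (i in seq_along(modules)) {
    gs <- modules[[i]]
    if (length(gs) < 2L) next
    prs <- utils::combn(gs, 2L)
    take <- stats::runif(ncol(prs)) <= module_edge_density
    if (!any(take)) next
    if (edge_type[i] == "experimental") {
      exp_edges[[length(exp_edges) + 1L]] <-
        data.frame(a = prs[1L, take], b = prs[2L, take], stringsAsFactors = FALSE)
    } else {
      str_edges[[length(str_edges) + 1L]] <-
        data.frame(a = prs[1L, take], b = prs[2L, take],
                   score = round(stats::runif(sum(take), string_score_range[1],
                                              string_score_range[2])),
                   stringsAsFactors = FALSE)
    }
  }
  if (background_density > 0 && length(all_genes) > 1L) {
    prs <- utils::combn(sort(all_genes), 2L)
    planted <- unlist(lapply(modules, function(gs)
      if (length(gs) > 1L) pair_key(utils::combn(gs, 2L)[1L, ],
                                    utils::combn(gs, 2L)[2L, ])))
    keys <- pair_key(prs[1L, ], prs[2L, ])
    take <- stats::runif(ncol(prs)) <= background_density & !(keys %in% planted)
    if (any(take))
      str_edges[[length(str_edges) + 1L]] <-
        data.frame(a = prs[1L, take], b = prs[2L, take],
                   score = round(stats::runif(sum(take), background_score_range[1],
                                              background_score_range[2])),
                   stringsAsFactors = FALSE)
  }
  interaction_network(
    experimental = if (length(exp_edges)) do.call(rbind, exp_edges),
    string = if (length(str_edges)) do.call(rbind, str_edges))
}

#' Simulate a complete TAPAS test scenario
#'
#' End-to-end fixture with planted co-expression + GO modules and decoy
#' queries:
#' * `n_modules` modules, each of `module_size` genes sharing a specific GO
#'   leaf term and a common expression bump; the module's query isoform is
#'   a high-TS minor isoform of a separate gene (annotated to the same
#'   leaf) whose profile matches the module bump while its primary isoform
#'   peaks elsewhere.
#' * Direct functional links are planted for a subset of modules
#'   (experimental edges, then a STRING-linked module); the remaining
#'   modules carry no edges and must be rescued by the average-similarity
#'   fallback.
#' * Decoy queries: one correlated with a group of root-only-annotated
#'   genes (coherence filter must discard it) and one with no correlated
#'   foreign transcript at all (insufficient annotation).
#'
#' @param seed RNG seed.
#' @param n_modules Number of planted modules (default 5).
#' @param module_size Genes per module (default 5).
#' @param n_stages Stages in the expression series (default 30).
#' @param noise_sigma Log-normal expression noise (default 0.05).
#' @param corpus_size Total annotated gene corpus (default 100).
#' @return List: `matrix`, `queries` (planted query transcript ids),
#'   `decoys` (decoy query transcript ids), `net`, `dag`, `ann`, `truth`
#'   (module assignment of each query), `module_terms`.
#' @export
simulate_tapas_scenario <- function(seed, n_modules = 5, module_size = 5,
                                    n_stages = 30, noise_sigma = 0.05,
                                    corpus_size = 100) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic simulation")
  stopifnot(n_modules <= 5, n_stages >= 30)
  set.seed(seed)
  w <- 1.2
  module_centres <- c(4, 9, 14, 19, 24)[seq_len(n_modules)]
  filler_centres <- c(6.5, 11.5, 16.5, 21.5)
  decoy_centres <- c(1.5, 28)
  lonely_centre <- 30

  module_genes <- lapply(stats::setNames(seq_len(n_modules),
                                         paste0("M", seq_len(n_modules))),
                         function(i) sprintf("M%d_G%02d", i, seq_len(module_size)))
  query_genes <- sprintf("QG%02d", seq_len(n_modules))
  decoy_query_genes <- c("DQ01", "DQ02", "DQ03")
  decoy_cluster_genes <- list(sprintf("DCA_G%02d", 1:6), sprintf("DCB_G%02d", 1:6))
  n_named <- n_modules * module_size + n_modules + length(decoy_query_genes) +
    sum(lengths(decoy_cluster_genes))
  filler_genes <- sprintf("BG_G%03d", seq_len(max(0, corpus_size - n_named)))

  profile <- function(centre, peak = 100)
    apply_lognormal_noise(bump_profile(n_stages, centre + stats::runif(1, -0.2, 0.2),
                                       w, peak), noise_sigma)
  rows <- list(); map <- character(); ann <- list()
  add <- function(tid, gene, prof) {
    rows[[tid]] <<- prof
    map[tid] <<- gene
  }
  root_ann <- character()

  for (i in seq_len(n_modules)) {
    for (g in module_genes[[i]]) add(paste0("T", g, ".1"), g, profile(module_centres[i]))
    qg <- query_genes[i]
    add(paste0("T", qg, ".1"), qg, profile(module_centres[i] - 2.5))  # primary
    add(paste0("T", qg, ".2"), qg, profile(module_centres[i], peak = 80))  # query minor
  }
  for (j in 1:2) {
    dq <- decoy_query_genes[j]
    add(paste0("T", dq, ".1"), dq, profile(filler_centres[j + 1]))
    add(paste0("T", dq, ".2"), dq, profile(decoy_centres[j], peak = 80))
    for (g in decoy_cluster_genes[[j]]) add(paste0("T", g, ".1"), g,
                                            profile(decoy_centres[j]))
  }
  dq3 <- decoy_query_genes[3]
  add(paste0("T", dq3, ".1"), dq3, profile(filler_centres[4]))
  add(paste0("T", dq3, ".2"), dq3, profile(lonely_centre, peak = 80))
  for (k in seq_along(filler_genes)) {
    g <- filler_genes[k]
    ctr <- filler_centres[(k - 1L) %% length(filler_centres) + 1L]
    add(paste0("T", g, ".1"), g, profile(ctr, peak = 30))
  }

  expr <- do.call(rbind, rows)
  colnames(expr) <- stage_labels(n_stages)
  m <- time_course_matrix(expr, map)

  go <- simulate_go(n_modules = n_modules,
                    module_genes = lapply(seq_len(n_modules), function(i)
                      c(module_genes[[i]], query_genes[i])),
                    background_genes = c(decoy_query_genes,
                                         unlist(decoy_cluster_genes), filler_genes),
                    seed = seed)

  link_type <- rep(c("experimental", "experimental", "string", "none", "none"),
                   length.out = n_modules)
  linked <- which(link_type != "none")
  net <- simulate_network(
    modules = lapply(linked, function(i) c(query_genes[i], module_genes[[i]])),
    edge_type = link_type[linked], seed = seed)

  list(matrix = m,
       queries = paste0("T", query_genes, ".2"),
       decoys = paste0("T", decoy_query_genes, ".2"),
       net = net, dag = go$dag, ann = go$ann,
       truth = data.frame(query = paste0("T", query_genes, ".2"),
                          module = names(module_genes),
                          planted_link = link_type, stringsAsFactors = FALSE),
       module_terms = go$module_terms)
}
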