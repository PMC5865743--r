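#' Synthetic scenario configuration
#'
#' Bundles every knob of the synthetic-cohort generator: pathway topology,
#' miRNA-gene interaction density, cohort size, the planted prognostic
#' signal, and the censoring regime.  Defaults describe a cohort of the
#' scale and character of a single-disease TCGA expression study: about a
#' hundred patients, FPKM-like skewed non-negative expression, median
#' survival around a year, roughly a third of follow-ups censored.
#'
#' @param n_pathways Number of pathway graphs to simulate.
#' @param genes_per_pathway Genes per pathway (must be at least 3, the
#'   minimum that can survive the subpathway size filter).
#' @param edge_prob Erdos-Renyi edge probability within a pathway; sparse
#'   draws are repaired to connectivity with minimal bridging edges.
#' @param n_mirnas Number of miRNAs.
#' @param interaction_prob Independent inclusion probability of each
#'   (miRNA, gene) interaction.
#' @param low_throughput_frac Fraction of interactions tagged as verified by
#'   low-throughput experiments (the rest are tagged high-throughput).
#' @param n_samples Cohort size.
#' @param planted_subpathway_count How many subpathways carry survival signal.
#' @param effect_size_beta Log hazard ratio per planted feature (on the
#'   standardized log2(FPKM+1) scale); 0 gives a null scenario.
#' @param baseline_hazard Baseline event rate per month (default gives a
#'   12-month median survival for a baseline patient).
#' @param censor_rate Expected fraction of samples censored.
#' @param min_followup Months of guaranteed follow-up before censoring can
#'   occur.
#' @param seed Master seed; per-artifact substreams use fixed offsets.
#' @return Validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_pathways = 20, genes_per_pathway = 8,
                            edge_prob = 0.35, n_mirnas = 40,
                            interaction_prob = 0.02,
                            low_throughput_frac = 0.8,
                            n_samples = 112,
                            planted_subpathway_count = 3,
                            effect_size_beta = 1.0,
                            baseline_hazard = log(2) / 12,
                            censor_rate = 0.3, min_followup = 1,
                            seed = 1L) {
  cfg <- list(
    n_pathways = as.integer(n_pathways),
    genes_per_pathway = as.integer(genes_per_pathway),
    edge_prob = edge_prob, n_mirnas = as.integer(n_mirnas),
    interaction_prob = interaction_prob,
    low_throughput_frac = low_throughput_frac,
    n_samples = as.integer(n_samples),
    planted_subpathway_count = as.integer(planted_subpathway_count),
    effect_size_beta = effect_size_beta,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, min_followup = min_followup,
    seed = as.integer(seed)
  )
  counts <- c("n_pathways", "genes_per_pathway", "n_mirnas", "n_samples")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop(f, " must be >= 1")
  }
  if (cfg$planted_subpathway_count < 0L) stop("planted_subpathway_count must be >= 0")
  if (cfg$genes_per_pathway < 3L) {
    stop("genes_per_pathway must be >= 3 (smaller pathways can never pass ",
         "the subpathway size filter)")
  }
  probs <- c("edge_prob", "interaction_prob", "low_throughput_frac", "censor_rate")
  for (f in probs) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must be a probability in [0, 1]")
    }
  }
  if (!is.finite(cfg$baseline_hazard) || cfg$baseline_hazard <= 0) {
    stop("baseline_hazard must be > 0")
  }
  if (cfg$min_followup < 0) stop("min_followup must be >= 0")
  structure(cfg, class = "scenario_config")
}

# Substream seeds: one master seed, fixed offsets per artifact, kept inside
# 32-bit integer range.
substream_seed <- function(cfg, offset) {
  as.integer((as.double(cfg$seed) + offset) %% (.Machine$integer.max - 1))
}

#' Simulate connected pathway graphs
#'
#' Each pathway is an Erdos-Renyi draw on its genes; if the draw is
#' disconnected, components are joined with the minimum number of bridging
#' edges, so `edge_prob = 0` yields a random tree.  Gene ids are globally
#' unique across pathways.
#'
#' @param cfg A [scenario_config()].
#' @return List of [pathway_graph()] objects.
#' @export
generate_pathways <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(substream_seed(cfg, 1))
  lapply(seq_len(cfg$n_pathways), function(i) {
    pid <- sprintf("9%04d", i)
    genes <- sprintf("g%s.%03d", pid, seq_len(cfg$genes_per_pathway))
    pairs <- t(utils::combn(genes, 2L))
    keep <- stats::runif(nrow(pairs)) < cfg$edge_prob
    edges <- pairs[keep, , drop = FALSE]
    edges <- bridge_components(genes, edges)
    pathway_graph(pid, pathway_name = sprintf("synthetic pathway %d", i),
                  nodes = genes, edges = edges)
  })
}

# Join graph components with n_components - 1 random bridging edges.
bridge_components <- function(nodes, edges) {
  ig <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = nodes)
  if (nrow(edges)) ig <- igraph::add_edges(ig, t(edges))
  comp <- igraph::components(ig)
  if (comp$no <= 1L) return(edges)
  members <- split(nodes, comp$membership)
  bridges <- vapply(seq_len(comp$no - 1L), function(i) {
    c(sample(members[[i]], 1L), sample(members[[i + 1L]], 1L))
  }, character(2L))
  rbind(edges, t(bridges))
}

#' Simulate a miRNA-gene interaction table
#'
#' Each (miRNA, gene) pair over all pathway genes is included independently
#' with `interaction_prob`; included rows are tagged `low-throughput` with
#' probability `low_throughput_frac`, otherwise `high-throughput`.
#'
#' @param pathways List of [pathway_graph()] objects (non-empty).
#' @param cfg A [scenario_config()].
#' @return Interaction data frame (`mirna`, `gene`, `evidence`).
#' @export
generate_interactions <- function(pathways, cfg) {
  stopifnot(inherits(cfg, "scenario_config"), length(pathways) > 0L)
  set.seed(substream_seed(cfg, 2))
  genes <- unlist(lapply(pathways, `[[`, "nodes"))
  mirnas <- mirna_ids(cfg)
  grid <- expand.grid(mirna = mirnas, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < cfg$interaction_prob
  tbl <- grid[keep, , drop = FALSE]
  tbl$evidence <- ifelse(stats::runif(nrow(tbl)) < cfg$low_throughput_frac,
                         "low-throughput", "high-throughput")
  rownames(tbl) <- NULL
  tbl
}

mirna_ids <- function(cfg) sprintf("mir-%03d", seq_len(cfg$n_mirnas))

#' Simulate an expression + survival cohort with planted subpathway signal
#'
#' Expression is log-normal (feature-specific location and scale), so values
#' are non-negative and right-skewed like FPKM.  Survival follows a
#' proportional-hazards model: each sample's hazard is
#' `baseline_hazard * exp(sum(beta_j * x_ij))` where `beta_j =
#' effect_size_beta` for every gene and miRNA belonging to a planted
#' subpathway and 0 otherwise, and `x` is the standardized log2(FPKM+1)
#' value — the same covariate scale the screening stage fits.  Event times
#' are exponential with that hazard; independent censoring times are
#' `min_followup` plus an exponential whose rate is solved numerically so the
#' expected censored fraction equals `censor_rate`.
#'
#' @param subpathways List of [subpathway_graph()] objects.
#' @param planted Character vector of subpathway ids carrying signal
#'   (must all be present in `subpathways`).
#' @param cfg A [scenario_config()].
#' @param pathways Optional pathway list defining the full gene universe;
#'   if omitted, the union of subpathway member genes is used.
#' @param mirnas Optional character vector defining the full miRNA universe;
#'   defaults to the `n_mirnas` ids the interaction generator uses.
#' @return List with elements `mirna_expr`, `gene_expr` (matrices, features x
#'   samples), `clinical` (data.frame `sample_id`, `time_months`, `event`)
#'   and `planted_features`.
#' @export
generate_cohort <- function(subpathways, planted, cfg,
                            pathways = NULL, mirnas = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  ids <- vapply(subpathways, `[[`, character(1L), "subpathway_id")
  bad <- setdiff(planted, ids)
  if (length(bad)) {
    stop("planted ids not among subpathways: ", paste(bad, collapse = ", "))
  }
  genes <- if (!is.null(pathways)) {
    unlist(lapply(pathways, `[[`, "nodes"))
  } else {
    sort(unique(unlist(lapply(subpathways, `[[`, "genes"))))
  }
  if (is.null(mirnas)) {
    mirnas <- sort(unique(c(mirna_ids(cfg),
                            unlist(lapply(subpathways, `[[`, "mirnas")))))
  }
  sel <- subpathways[ids %in% planted]
  planted_features <- sort(unique(unlist(lapply(sel, function(s) {
    c(s$genes, s$mirnas)
  }))))

  set.seed(substream_seed(cfg, 3))
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  gene_expr <- lognormal_matrix(genes, samples)
  mirna_expr <- lognormal_matrix(mirnas, samples)

  expr_all <- rbind(gene_expr, mirna_expr)
  x <- standardize_log2(expr_all)
  beta <- numeric(nrow(x))
  names(beta) <- rownames(x)
  beta[intersect(planted_features, names(beta))] <- cfg$effect_size_beta
  lp <- as.numeric(crossprod(x, beta))
  hazard <- cfg$baseline_hazard * exp(lp)
  event_time <- stats::rexp(n, rate = hazard)

  if (cfg$censor_rate <= 0) {
    time <- event_time
    event <- rep(1L, n)
  } else {
    crate <- solve_censor_rate(hazard, cfg$censor_rate, cfg$min_followup)
    censor_time <- cfg$min_followup + stats::rexp(n, rate = crate)
    event <- as.integer(event_time <= censor_time)
    time <- pmin(event_time, censor_time)
  }
  clinical <- data.frame(sample_id = samples, time_months = time,
                         event = event, stringsAsFactors = FALSE)
  list(mirna_expr = mirna_expr, gene_expr = gene_expr, clinical = clinical,
       planted_features = planted_features)
}

lognormal_matrix <- function(features, samples) {
  p <- length(features); n <- length(samples)
  meanlog <- stats::rnorm(p, mean = 2, sd = 1)
  sdlog <- stats::runif(p, 0.4, 1.2)
  z <- matrix(stats::rnorm(p * n), nrow = p)
  m <- exp(meanlog + sdlog * z)
  dimnames(m) <- list(features, samples)
  m
}

# Standardize log2(x + 1) per feature; zero-variance rows map to all zeros.
standardize_log2 <- function(m) {
  lx <- log2(m + 1)
  mu <- rowMeans(lx)
  s <- apply(lx, 1L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  (lx - mu) / s
}

# Censoring time is min_followup + Exp(c); with T_i ~ Exp(h_i) independent,
# P(censored_i) = exp(-h_i * m) * c / (c + h_i).  Solve the mean over samples
# for c.
solve_censor_rate <- function(hazard, target, min_followup) {
  pmax_attain <- mean(exp(-hazard * min_followup))
  if (target >= pmax_attain) {
    warning("censor_rate ", target, " unattainable with min_followup ",
            min_followup, "; using the attainable maximum")
    return(1e6)
  }
  f <- function(logc) {
    c <- exp(logc)
    mean(exp(-hazard * min_followup) * c / (c + hazard)) - target
  }
  root <- stats::uniroot(f, lower = log(1e-8), upper = log(1e6),
                         tol = 1e-10, extendInt = "upX")
  exp(root$root)
}

#' Write a full synthetic scenario to disk in the pipeline's input formats
#'
#' Runs the three generators, builds the filtered miRNA-embedded subpathways,
#' picks the planted set, and writes expression, clinical, interaction and
#' subpathway files exactly as the analysis stages read them.
#'
#' @param cfg A [scenario_config()].
#' @param outdir Output directory (created if needed).
#' @param k,min_mirnas,min_genes,evidence_filter Subpathway construction
#'   settings used when realising the scenario.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_scenario <- function(cfg, outdir, k = 3, min_mirnas = 1,
                              min_genes = 3,
                              evidence_filter = "low-throughput") {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pathways <- generate_pathways(cfg)
  interactions <- generate_interactions(pathways, cfg)
  subs <- build_subpathways(pathways, interactions, k = k,
                            min_mirnas = min_mirnas, min_genes = min_genes,
                            evidence_filter = evidence_filter)
  ids <- vapply(subs, `[[`, character(1L), "subpathway_id")
  n_plant <- min(cfg$planted_subpathway_count, length(ids))
  set.seed(substream_seed(cfg, 4))
  planted <- sort(sample(ids, n_plant))
  cohort <- generate_cohort(subs, planted, cfg, pathways = pathways)
  paths <- list(
    mirna_expr = file.path(outdir, "mirna_expression.tsv"),
    gene_expr = file.path(outdir, "gene_expression.tsv"),
    clinical = file.path(outdir, "clinical.tsv"),
    interactions = file.path(outdir, "interactions.tsv"),
    subpathways = file.path(outdir, "subpathways.json"),
    planted = file.path(outdir, "planted.json")
  )
  write_expression_tsv(cohort$mirna_expr, paths$mirna_expr, "mirna_id")
  write_expression_tsv(cohort$gene_expr, paths$gene_expr, "gene_id")
  write_clinical_tsv(cohort$clinical, paths$clinical)
  write_interactions_tsv(interactions, paths$interactions)
  write_subpathways_json(subs, paths$subpathways)
  jsonlite::write_json(as.list(planted), paths$planted)
  invisible(list(pathways = pathways, interactions = interactions,
                 subpathways = subs, planted = planted, cohort = cohort,
                 paths = paths))
}
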