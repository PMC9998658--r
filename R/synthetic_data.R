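#' @title Synthetic-data generators
#' @description Seeded generators for LFQ datasets (with bead-control
#'   background, condition-specific spiked interactors and MNAR/MAR
#'   dropout), effector networks, GO DAGs with annotations, and phenotype
#'   tables. Every generator is fully determined by its seed and returns
#'   the ground truth needed for recovery tests.
#' @name synthetic_data
NULL

#' Simulation configuration for a synthetic LFQ dataset
#'
#' Defaults emulate the study design the pipeline targets: 4 genetic x 11
#' culture contexts, 3 biological x 2 technical replicates (264 sample runs)
#' plus 6 bead-control runs; log2-normal background shared with the bead
#' controls; a fraction of proteins spiked as condition-specific true
#' interactors; and both intensity-dependent (MNAR) and uniform (MAR)
#' dropout.
#'
#' @param n_proteins number of proteins.
#' @param grid condition grid from [design_grid()].
#' @param n_bio,n_tech replicates per condition.
#' @param n_control_bio,n_control_tech bead-control replicates.
#' @param frac_true_interactors fraction of proteins spiked per condition.
#' @param enrichment_logfc mean spike above control, log2 units.
#' @param sigma_bio,sigma_tech biological/technical noise SD, log2 units.
#' @param mnar_rate,mar_rate target dropout fractions.
#' @param baseline_mu,baseline_sigma log2-normal background parameters.
#' @param seed integer; fully determines the output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_proteins = 200,
                       grid = design_grid(),
                       n_bio = grid$n_bio, n_tech = grid$n_tech,
                       n_control_bio = 3, n_control_tech = 2,
                       frac_true_interactors = 0.10,
                       enrichment_logfc = 2.0,
                       sigma_bio = 0.5, sigma_tech = 0.2,
                       mnar_rate = 0.10, mar_rate = 0.05,
                       baseline_mu = 25, baseline_sigma = 1.5,
                       seed = 1L) {
  stopifnot(mnar_rate >= 0, mnar_rate <= 1, mar_rate >= 0, mar_rate <= 1,
            sigma_bio > 0, sigma_tech > 0, baseline_sigma > 0)
  structure(list(
    n_proteins = n_proteins, grid = grid, n_bio = n_bio, n_tech = n_tech,
    n_control_bio = n_control_bio, n_control_tech = n_control_tech,
    frac_true_interactors = frac_true_interactors,
    enrichment_logfc = enrichment_logfc,
    sigma_bio = sigma_bio, sigma_tech = sigma_tech,
    mnar_rate = mnar_rate, mar_rate = mar_rate,
    baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate an LFQ dataset with bead controls and planted interactors
#'
#' Background log2 intensities are Normal(`baseline_mu`, `baseline_sigma`)
#' per protein, shared between sample and bead-control runs, with
#' per-biological-replicate noise (`sigma_bio`) and per-run technical noise
#' (`sigma_tech`). Per condition, a seeded random subset of proteins
#' (`frac_true_interactors`) is spiked by `enrichment_logfc` log2 units in
#' that condition's sample runs only; bead controls never receive spikes.
#' MAR dropout is uniform at `mar_rate`; MNAR dropout probability is
#' logistic, decreasing in log2 intensity, with its intercept calibrated so
#' the realized MNAR rate matches `mnar_rate`. Dropped cells are set to 0
#' (the raw-export non-observation convention).
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (raw-scale [lfq_dataset()]) and `truth`
#'   (list: `true_interactors` per condition, `mnar_mask`, `mar_mask`,
#'   `baseline_log2`).
#' @export
simulate_lfq <- function(config) {
  cfg <- config
  n_spike <- floor(cfg$frac_true_interactors * cfg$n_proteins)
  if (cfg$frac_true_interactors > 0 && n_spike < 1)
    stop("frac_true_interactors * n_proteins < 1: no protein to spike")

  conds <- cfg$grid$conditions
  runs <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    expand.grid(bio_rep = seq_len(cfg$n_bio), tech_rep = seq_len(cfg$n_tech),
                KEEP.OUT.ATTRS = FALSE) -> rr
    cbind(genetic_context = conds$genetic_context[i],
          culture_context = conds$culture_context[i],
          concentration = conds$concentration[i], rr,
          is_control = FALSE, stringsAsFactors = FALSE)
  }))
  ctrl <- expand.grid(bio_rep = seq_len(cfg$n_control_bio),
                      tech_rep = seq_len(cfg$n_control_tech),
                      KEEP.OUT.ATTRS = FALSE)
  ctrl <- cbind(genetic_context = CONTROL_SENTINEL,
                culture_context = CONTROL_SENTINEL,
                concentration = CONTROL_SENTINEL, ctrl,
                is_control = TRUE, stringsAsFactors = FALSE)
  runs <- rbind(runs, ctrl)
  runs$run_id <- ifelse(runs$is_control,
    sprintf("ctrl_b%d_t%d", runs$bio_rep, runs$tech_rep),
    sprintf("%s_%s_%s_b%d_t%d", runs$genetic_context, runs$culture_context,
            runs$concentration, runs$bio_rep, runs$tech_rep))
  runs <- runs[c("run_id", "genetic_context", "culture_context",
                 "concentration", "bio_rep", "tech_rep", "is_control")]
  rownames(runs) <- NULL

  P <- cfg$n_proteins
  R <- nrow(runs)
  cond_lab <- ifelse(runs$is_control, CONTROL_SENTINEL,
                     paste(runs$genetic_context, runs$culture_context,
                           runs$concentration, sep = "."))
  uc <- unique(cond_lab[!runs$is_control])

  withr_seed(cfg$seed, {
    baseline <- stats::rnorm(P, cfg$baseline_mu, cfg$baseline_sigma)
    true_int <- lapply(uc, function(cl) sort(sample.int(P, n_spike)))
    names(true_int) <- uc

    log2m <- matrix(baseline, P, R)
    # biological noise: one draw per (protein, condition-label, bio rep)
    bio_key <- paste(cond_lab, runs$bio_rep)
    for (bk in unique(bio_key)) {
      cols <- which(bio_key == bk)
      eb <- stats::rnorm(P, 0, cfg$sigma_bio)
      log2m[, cols] <- log2m[, cols] + eb
    }
    log2m <- log2m + matrix(stats::rnorm(P * R, 0, cfg$sigma_tech), P, R)
    for (cl in uc) {
      cols <- which(cond_lab == cl)
      log2m[true_int[[cl]], cols] <- log2m[true_int[[cl]], cols] +
        cfg$enrichment_logfc
    }

    mar_mask <- matrix(stats::runif(P * R) < cfg$mar_rate, P, R)
    mnar_mask <- matrix(FALSE, P, R)
    if (cfg$mnar_rate > 0) {
      free <- !mar_mask
      x <- log2m[free]
      x0 <- stats::median(x)
      target <- min(cfg$mnar_rate / max(1 - cfg$mar_rate, 1e-9), 0.999)
      f <- function(c0) mean(stats::plogis(c0 - (x - x0))) - target
      c0 <- stats::uniroot(f, c(-50, 50))$root
      pdrop <- matrix(0, P, R)
      pdrop[free] <- stats::plogis(c0 - (log2m[free] - x0))
      mnar_mask <- matrix(stats::runif(P * R) < pdrop, P, R) & free
    }
  })

  raw <- 2 ^ log2m
  raw[mar_mask | mnar_mask] <- 0

  proteins <- data.frame(
    protein_id = sprintf("P%04d", seq_len(P)),
    gene_name = sprintf("GENE%04d", seq_len(P)),
    flag_site_only = FALSE, flag_contaminant = FALSE, flag_reverse = FALSE,
    stringsAsFactors = FALSE)
  ds <- lfq_dataset(raw, runs, proteins, log2_scale = FALSE)
  truth <- list(
    true_interactors = lapply(true_int, function(ix) proteins$protein_id[ix]),
    mnar_mask = mnar_mask, mar_mask = mar_mask,
    baseline_log2 = baseline)
  list(dataset = ds, truth = truth)
}

#' Plant a factor effect on one GO term's proteins
#'
#' Adds `logfc` log2 units to the intensities of every protein annotated to
#' `term`, in all sample runs whose `factor_name` equals `level`. Used to
#' test that the term-level ANOVA scan recovers planted effects.
#'
#' @param ds a raw-scale `lfq_dataset`.
#' @param annotations data.frame (`gene`, `term`); genes matched against
#'   `ds$proteins$gene_name`.
#' @param term the term to perturb.
#' @param factor_name one of `"genetic_context"`, `"culture_context"`,
#'   `"concentration"`.
#' @param level the factor level receiving the effect.
#' @param logfc effect size, log2 units.
#' @return the modified dataset.
#' @export
plant_term_effect <- function(ds, annotations, term, factor_name, level, logfc) {
  genes <- annotations$gene[annotations$term == term]
  rows <- which(ds$proteins$gene_name %in% genes)
  cols <- which(!ds$runs$is_control & ds$runs[[factor_name]] == level)
  if (!length(rows) || !length(cols)) return(ds)
  obs <- !is.na(ds$intensity[rows, cols, drop = FALSE]) &
    ds$intensity[rows, cols, drop = FALSE] > 0
  fac <- if (ds$log2_scale) logfc else NULL
  if (ds$log2_scale) {
    ds$intensity[rows, cols][obs] <- ds$intensity[rows, cols][obs] + logfc
  } else {
    ds$intensity[rows, cols][obs] <- ds$intensity[rows, cols][obs] * 2^logfc
  }
  ds
}

#' Simulate an effector network
#'
#' A connected undirected graph (random spanning tree plus uniformly placed
#' extra edges to hit the requested mean degree) with edge confidence scores
#' Uniform(0.5, 1), a designated source (bait) node connected by directed
#' edges to `n_effectors` designated effector nodes. The raw scored edge
#' list is attached so that a confidence filter can be applied via
#' [build_network()].
#'
#' @param n_nodes number of non-source nodes.
#' @param mean_degree target mean degree of the undirected graph.
#' @param n_effectors number of effector nodes.
#' @param seed integer seed.
#' @param source_id name of the source node.
#' @param node_names optional node names (length `n_nodes`); default
#'   `N001..`.
#' @return an `effector_network` (see [build_network()]); the raw edge
#'   table is in the `"edge_table"` attribute.
#' @export
simulate_network <- function(n_nodes, mean_degree, n_effectors, seed = 1L,
                             source_id = "KRAS", node_names = NULL) {
  stopifnot(n_nodes >= 3, n_effectors >= 1, n_effectors <= n_nodes)
  nodes <- node_names %||% sprintf("N%03d", seq_len(n_nodes))
  stopifnot(length(nodes) == n_nodes, !source_id %in% nodes)
  target_edges <- round(n_nodes * mean_degree / 2)
  withr_seed(seed, {
    # random spanning tree: connect node i to a uniform earlier node
    perm <- sample(nodes)
    a <- perm[vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), 1L)]
    b <- perm[2:n_nodes]
    key <- paste(pmin(a, b), pmax(a, b))
    extra_needed <- max(0L, target_edges - (n_nodes - 1L))
    while (extra_needed > 0L) {
      na_ <- sample(nodes, 2L * extra_needed, replace = TRUE)
      nb_ <- sample(nodes, 2L * extra_needed, replace = TRUE)
      ok <- na_ != nb_
      k2 <- paste(pmin(na_, nb_), pmax(na_, nb_))[ok]
      k2 <- k2[!duplicated(k2) & !k2 %in% key]
      take <- utils::head(k2, extra_needed)
      key <- c(key, take)
      extra_needed <- extra_needed - length(take)
    }
    parts <- strsplit(key, " ", fixed = TRUE)
    edges <- data.frame(node_a = vapply(parts, `[`, "", 1),
                        node_b = vapply(parts, `[`, "", 2),
                        score = stats::runif(length(key), 0.5, 1.0),
                        stringsAsFactors = FALSE)
    effectors <- sort(sample(nodes, n_effectors))
  })
  net <- build_network(edges, effectors, source_id, min_score = 0,
                       max_sp = Inf)
  attr(net, "edge_table") <- edges
  net
}

#' Simulate a GO DAG and gene annotations
#'
#' A rooted DAG of `n_terms` terms: the root is term 1; each later term
#' attaches to 1-2 uniformly chosen existing terms at depth < `max_depth`
#' (edge type `is_a`, with a small fraction `part_of`). Each gene receives
#' 1-5 annotations to leaf terms.
#'
#' @param n_terms number of terms (>= 2).
#' @param max_depth maximum term depth (root = 0).
#' @param genes character vector of gene ids to annotate.
#' @param seed integer seed.
#' @param part_of_frac fraction of `part_of` edges.
#' @return list with `dag` (a `go_dag`) and `annotations`
#'   (data.frame `gene`, `term`).
#' @export
simulate_go <- function(n_terms, max_depth = 4, genes, seed = 1L,
                        part_of_frac = 0.1) {
  stopifnot(n_terms >= 2, max_depth >= 1)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  withr_seed(seed, {
    depth <- c(0L, rep(NA_integer_, n_terms - 1L))
    child <- character(); parent <- character(); type <- character()
    for (i in 2:n_terms) {
      eligible <- which(!is.na(depth[seq_len(i - 1L)]) &
                        depth[seq_len(i - 1L)] < max_depth)
      np <- min(length(eligible), sample(1:2, 1L))
      ps <- if (length(eligible) == 1L) eligible else sample(eligible, np)
      depth[i] <- max(depth[ps]) + 1L
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ids[ps])
      type <- c(type, ifelse(stats::runif(length(ps)) < part_of_frac,
                             "part_of", "is_a"))
    }
    leaves <- setdiff(ids, parent)
    ann <- do.call(rbind, lapply(genes, function(g) {
      k <- min(length(leaves), sample(1:5, 1L))
      data.frame(gene = g,
                 term = if (length(leaves) == 1L) leaves else sample(leaves, k),
                 stringsAsFactors = FALSE)
    }))
  })
  terms <- data.frame(id = ids, name = paste("term", seq_len(n_terms)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = child, parent = parent, type = type,
                      stringsAsFactors = FALSE)
  ann <- unique(ann); rownames(ann) <- NULL
  list(dag = go_dag(terms, edges), annotations = ann)
}

#' Simulate a phenotype table
#'
#' Parameter x group measurements with per-group means drawn from a seeded
#' normal and replicate noise, for exercising the factorial-ANOVA and
#' correlation operations.
#'
#' @param parameters character vector of parameter names.
#' @param groups data.frame of group factors (one row per group).
#' @param n_rep replicates per group.
#' @param effect_sd SD of group means; `noise_sd` SD of replicate noise.
#' @param noise_sd replicate noise SD.
#' @param seed integer seed.
#' @return data.frame in long format: `parameter`, group factor columns,
#'   `replicate`, `value`.
#' @export
simulate_phenotype <- function(parameters, groups, n_rep = 3,
                               effect_sd = 1, noise_sd = 0.3, seed = 1L) {
  withr_seed(seed, {
    out <- do.call(rbind, lapply(parameters, function(pp) {
      mu <- stats::rnorm(nrow(groups), 10, effect_sd)
      do.call(rbind, lapply(seq_len(nrow(groups)), function(gi) {
        data.frame(parameter = pp, groups[gi, , drop = FALSE],
                   replicate = seq_len(n_rep),
                   value = mu[gi] + stats::rnorm(n_rep, 0, noise_sd),
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    }))
  })
  rownames(out) <- NULL
  out
}
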