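#' @title Pipeline orchestration
#' @description One-config reproducible runs: simulate -> filter ->
#'   differential/GSEA -> collapse/ANOVA -> semantic clustering -> biased
#'   walks, each stage writing TSV artifacts and a manifest recording the
#'   config hash and per-stage row counts. Stages are pure functions of
#'   their inputs and seeds, so a rerun with the same config is identical.
#' @name pipeline_cli
NULL

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived deterministically
#'   (small offsets, all below 2^31).
#' @param sim list of overrides for [sim_config()].
#' @param filter list of parameter overrides for [run_filter_pipeline()].
#' @param go list: `n_terms`, `max_depth`.
#' @param gsea list: `n_perm`, `weight`; `condition` (label or `NULL` for
#'   the first).
#' @param walk list: `n_nodes`, `mean_degree`, `n_effectors`, `n_walks`,
#'   `bias_factor`, `min_freq`, `top_k`, `n_targets`, `min_score`,
#'   `max_sp`.
#' @param stages character vector of stages to run, in order.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("apmswalk_run_"),
                            seed = 1L,
                            sim = list(), filter = list(),
                            go = list(), gsea = list(), walk = list(),
                            stages = c("simulate", "filter", "gsea",
                                       "collapse", "semantic", "walk")) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    sim = utils::modifyList(list(n_proteins = 120), sim),
    filter = filter,
    go = utils::modifyList(list(n_terms = 40, max_depth = 4), go),
    gsea = utils::modifyList(list(n_perm = 200, weight = 1,
                                  condition = NULL), gsea),
    walk = utils::modifyList(list(n_nodes = 60, mean_degree = 5,
                                  n_effectors = 5, n_walks = 20000,
                                  bias_factor = 20, min_freq = 1e-6,
                                  top_k = 10, n_targets = 3,
                                  min_score = 0.7, max_sp = 4), walk))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(cfg, k) (cfg$seed * 101L + k) %% .Machine$integer.max

#' Run the full pipeline from one configuration
#'
#' Stages execute in order; each writes its TSV artifacts under
#' `config$out_dir` and appends row counts to the manifest. A stage whose
#' upstream artifact is missing (because the producing stage was disabled)
#' fails with a message naming the missing stage.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   `manifest` (also written to `manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), stages = list())
  res <- list()
  t0 <- Sys.time()
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs the output of disabled stage '",
           what, "'")
  }
  log_stage <- function(name, counts) {
    manifest$stages[[name]] <<- counts
    message("[apmswalk] stage ", name, ": ",
            paste(names(counts), unlist(counts), sep = "=", collapse = ", "))
  }

  if ("simulate" %in% cfg$stages) {
    sim_args <- utils::modifyList(cfg$sim, list(seed = stage_seed(cfg, 1L)))
    sc <- do.call(sim_config, sim_args)
    sim <- simulate_lfq(sc)
    gg <- simulate_go(cfg$go$n_terms, cfg$go$max_depth,
                      genes = sim$dataset$proteins$gene_name,
                      seed = stage_seed(cfg, 2L))
    nn <- min(cfg$walk$n_nodes, nrow(sim$dataset$proteins))
    net <- simulate_network(nn, cfg$walk$mean_degree,
                            min(cfg$walk$n_effectors, nn - 1L),
                            seed = stage_seed(cfg, 3L),
                            node_names = utils::head(
                              sim$dataset$proteins$gene_name, nn))
    write_protein_groups(sim$dataset,
                         file.path(cfg$out_dir, "protein_groups.tsv"),
                         file.path(cfg$out_dir, "run_metadata.tsv"))
    write_edge_list(attr(net, "edge_table"),
                    file.path(cfg$out_dir, "network_edges.tsv"))
    write_obo(gg$dag, file.path(cfg$out_dir, "ontology.obo"))
    write_gaf(gg$annotations, file.path(cfg$out_dir, "annotations.tsv"))
    res$simulate <- list(sim = sim, go = gg, network = net)
    log_stage("simulate", list(proteins = nrow(sim$dataset$intensity),
                               runs = ncol(sim$dataset$intensity),
                               terms = nrow(gg$dag$terms),
                               network_nodes = length(net$nodes)))
  }

  if ("filter" %in% cfg$stages) {
    need("simulate", "filter")
    fp <- utils::modifyList(cfg$filter, list(seed = stage_seed(cfg, 4L)))
    flt <- run_filter_pipeline(res$simulate$sim$dataset, fp)
    calls <- do.call(rbind, flt$calls)
    if (!is.null(calls)) {
      write_tsv_strict(calls, file.path(cfg$out_dir, "interactor_calls.tsv"))
    }
    write_tsv_strict(flt$report, file.path(cfg$out_dir, "filter_report.tsv"))
    m <- flt$dataset$intensity
    write_tsv_strict(data.frame(protein_id = rownames(m), m,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "filtered_log2_matrix.tsv"))
    res$filter <- flt
    log_stage("filter", list(conditions = length(flt$calls),
                             called_total = sum(vapply(flt$interactors,
                                                       length, 1L))))
  }

  if ("gsea" %in% cfg$stages) {
    need("filter", "gsea")
    need("simulate", "gsea")
    calls <- Filter(Negate(is.null), res$filter$calls)
    if (length(calls)) {
      cond <- cfg$gsea$condition %||% names(calls)[1]
      d <- calls[[cond]]
      gmap <- res$simulate$sim$dataset$proteins
      score <- stats::setNames(d$stat,
                               gmap$gene_name[match(d$protein_id,
                                                    gmap$protein_id)])
      prop <- propagate_annotations(res$simulate$go$dag,
                                    res$simulate$go$annotations)
      sets <- split(prop$gene, prop$term)
      gs <- try(gsea_scan(score, sets, weight = cfg$gsea$weight,
                          n_perm = cfg$gsea$n_perm,
                          seed = stage_seed(cfg, 5L)), silent = TRUE)
      if (!inherits(gs, "try-error")) {
        write_tsv_strict(gs, file.path(cfg$out_dir, "gsea_results.tsv"))
        res$gsea <- gs
        log_stage("gsea", list(condition = cond, terms = nrow(gs)))
      }
    }
  }

  if ("collapse" %in% cfg$stages) {
    need("filter", "collapse")
    need("simulate", "collapse")
    prop <- propagate_annotations(res$simulate$go$dag,
                                  res$simulate$go$annotations)
    tim <- collapse_to_terms(res$filter$dataset, prop)
    smp <- !res$filter$dataset$runs$is_control
    design <- res$filter$dataset$runs[smp, c("genetic_context",
                                             "culture_context",
                                             "concentration")]
    scan <- term_anova_scan(tim[, smp, drop = FALSE], design)
    if (!is.null(scan$anova))
      write_tsv_strict(scan$anova, file.path(cfg$out_dir, "term_anova.tsv"))
    if (!is.null(scan$tukey))
      write_tsv_strict(scan$tukey, file.path(cfg$out_dir, "term_tukey.tsv"))
    res$collapse <- list(tim = tim, scan = scan)
    log_stage("collapse", list(terms = nrow(tim),
                               significant = if (is.null(scan$anova)) 0L
                               else length(unique(scan$anova$term[
                                 !is.na(scan$anova$p_hommel) &
                                   scan$anova$p_hommel < 0.05]))))
  }

  if ("semantic" %in% cfg$stages) {
    need("collapse", "semantic")
    need("simulate", "semantic")
    an <- res$collapse$scan$anova
    terms <- if (!is.null(an))
      unique(an$term[!is.na(an$p_hommel) & an$p_hommel < 0.05])
    else character()
    if (length(terms) < 2) terms <- utils::head(rownames(res$collapse$tim), 10)
    sim <- wang_similarity_matrix(res$simulate$go$dag, terms)
    cl <- binary_cut_cluster(sim)
    write_tsv_strict(data.frame(term = names(cl$labels),
                                cluster = unname(cl$labels)),
                     file.path(cfg$out_dir, "semantic_clusters.tsv"))
    res$semantic <- cl
    log_stage("semantic", list(terms = length(cl$labels),
                               clusters = length(unique(cl$labels))))
  }

  if ("walk" %in% cfg$stages) {
    need("simulate", "walk")
    need("filter", "walk")
    net <- res$simulate$network
    gmap <- res$simulate$sim$dataset$proteins
    conds <- names(Filter(function(x) length(x) > 0, res$filter$interactors))
    conds <- utils::head(conds, 2)
    targets <- utils::head(setdiff(net$nodes, net$effectors),
                           cfg$walk$n_targets)
    per_cond <- list()
    for (cl in conds) {
      ev <- gmap$gene_name[match(res$filter$interactors[[cl]],
                                 gmap$protein_id)]
      ev <- intersect(ev, net$nodes)
      rps <- list()
      for (tg in targets) {
        sp <- walk_spec(tg, n_walks = cfg$walk$n_walks, evidence = ev,
                        bias_factor = cfg$walk$bias_factor,
                        seed = stage_seed(cfg, 6L + match(tg, targets)))
        pe <- run_walks(net, sp)
        rps[[tg]] <- filter_and_rank_paths(pe, cfg$walk$min_freq,
                                           cfg$walk$top_k)
      }
      per_cond[[cl]] <- rps
      cn <- condition_network(rps)
      write_tsv_strict(cn, file.path(cfg$out_dir,
                                     paste0("flow_", gsub("[^A-Za-z0-9]", "_",
                                                          cl), ".tsv")))
    }
    if (length(per_cond)) {
      etm <- effector_traversal_matrix(per_cond, net$effectors)
      write_tsv_strict(data.frame(effector = rownames(etm), etm,
                                  check.names = FALSE),
                       file.path(cfg$out_dir, "effector_traversal.tsv"))
      res$walk <- list(per_condition = per_cond, traversal = etm)
      log_stage("walk", list(conditions = length(per_cond),
                             targets = length(targets)))
    }
  }

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  yaml::write_yaml(manifest[c("config_md5", "stages")],
                   file.path(cfg$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
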