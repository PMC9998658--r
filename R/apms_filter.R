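#' @title Five-step high-confidence interactor calling
#' @description The filtering cascade that turns a raw LFQ protein-groups
#'   matrix into per-condition lists of high-confidence bait interactors:
#'   (i) removal of flagged proteins (site-only / contaminant / reverse);
#'   (ii) zero-intensity observations become missing; (iii) outlier-run
#'   removal; (iv) a 60% within-group presence filter; (v) mixed
#'   imputation followed by a moderated test of each condition against the
#'   bead-only control, BH adjustment, and calling at p_adj < 0.01 and
#'   log2 fold change > 1. Technical replicates are merged by the median.
#' @name apms_filter
NULL

#' Step (i): remove flagged proteins
#'
#' Drops every protein carrying any of the three identification flags
#' ("only identified by site", "potential contaminant", "reverse").
#'
#' @param ds an `lfq_dataset`.
#' @return the filtered dataset; removed count in the `"n_removed"`
#'   attribute.
#' @export
remove_flagged <- function(ds) {
  bad <- ds$proteins$flag_site_only | ds$proteins$flag_contaminant |
    ds$proteins$flag_reverse
  if (all(bad)) warning("all proteins flagged; dataset is empty")
  out <- subset_lfq(ds, proteins = !bad)
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Step (ii): zero observations become missing
#'
#' A raw LFQ intensity of 0 is a non-observation, not a measured abundance;
#' those cells become `NA`. Matrix shape is unchanged.
#'
#' @param ds a raw-scale `lfq_dataset`.
#' @return the dataset with zeros replaced by `NA`.
#' @export
drop_zero_observations <- function(ds) {
  z <- !is.na(ds$intensity) & ds$intensity == 0
  ds$intensity[z] <- NA_real_
  attr(ds, "n_zeroed") <- sum(z)
  ds
}

#' Step (iii): detect outlier runs by low overall intensity
#'
#' A run is flagged iff its observed-protein count falls below
#' `min_proteins` (default: 50% of the cohort's median count) or its median
#' log2 intensity falls below the global median of run medians by more than
#' `mad_k` MADs.
#'
#' @param ds an `lfq_dataset` after zero removal.
#' @param min_proteins absolute count threshold; `NULL` for the default.
#' @param mad_k MAD multiplier for the intensity rule.
#' @return character vector of flagged run ids (possibly empty).
#' @export
detect_outlier_runs <- function(ds, min_proteins = NULL, mad_k = 3) {
  counts <- colSums(!is.na(ds$intensity))
  if (is.null(min_proteins)) min_proteins <- 0.5 * stats::median(counts)
  m <- ds$intensity
  if (!ds$log2_scale) m <- log2(m)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  centre <- stats::median(med, na.rm = TRUE)
  spread <- stats::mad(med, na.rm = TRUE)
  flagged <- counts < min_proteins |
    (is.finite(med) & med < centre - mad_k * spread)
  flagged[is.na(flagged)] <- TRUE
  if (all(flagged)) stop("all runs flagged as outliers")
  colnames(ds$intensity)[flagged]
}

#' Step (iv): within-group presence filter
#'
#' A group is the set of runs (biological x technical replicates) of one
#' condition, after outlier removal; bead controls form their own group.
#' A protein is kept for a group iff observed in at least `min_frac` of the
#' group's remaining runs, and removed globally only if it survives in no
#' group.
#'
#' @param ds an `lfq_dataset` after zero removal / outlier removal.
#' @param min_frac required presence fraction (default 0.6).
#' @return the globally filtered dataset; the per-(protein, group) keep
#'   matrix is in the `"group_keep"` attribute.
#' @export
presence_filter <- function(ds, min_frac = 0.6) {
  groups <- condition_of(ds)
  gl <- unique(groups)
  obs <- !is.na(ds$intensity)
  keep <- sapply(gl, function(g) {
    cols <- groups == g
    rowSums(obs[, cols, drop = FALSE]) / sum(cols) >= min_frac
  })
  keep <- matrix(keep, nrow = nrow(obs), dimnames = list(rownames(obs), gl))
  any_keep <- rowSums(keep) > 0
  out <- subset_lfq(ds, proteins = any_keep)
  attr(out, "group_keep") <- keep[any_keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!any_keep)
  out
}

#' Step (v): moderated enrichment test against the bead control
#'
#' For one condition: the condition's sample runs are compared with the
#' bead-control runs. Missing cells are classified MNAR/MAR
#' ([classify_missingness()]) and imputed ([impute_mixed()]; kNN for MAR, a
#' detection-limit floor for MNAR by default), the empirical-Bayes moderated
#' t is computed per protein, p-values are BH-adjusted across proteins
#' within the condition, and interactors are called at
#' `p_adj < alpha` and `log_fc > lfc`.
#'
#' @param ds a log2-scale `lfq_dataset` containing the condition and
#'   control runs.
#' @param condition condition label as produced by [condition_of()].
#' @param proteins optional protein ids to test (e.g. the condition's
#'   presence-filter survivors); default all.
#' @param alpha,lfc calling cutoffs (defaults 0.01 and 1).
#' @param strategy_mar,strategy_mnar imputation strategies.
#' @param k kNN neighbours.
#' @param moderate use empirical-Bayes moderation (default TRUE).
#' @param seed seed for stochastic imputation strategies.
#' @return data.frame of interactor calls: `condition`, `protein_id`,
#'   `log_fc`, `stat`, `p`, `p_adj`, `called`; or `NULL` (with a warning)
#'   when either side has fewer than 2 usable runs.
#' @export
control_enrichment <- function(ds, condition, proteins = NULL,
                               alpha = 0.01, lfc = 1,
                               strategy_mar = "knn",
                               strategy_mnar = "zero_floor",
                               k = 10, moderate = TRUE, seed = 1L) {
  if (!ds$log2_scale) stop("control_enrichment expects log2 scale")
  lab <- condition_of(ds)
  cc <- which(lab == condition)
  ct <- which(ds$runs$is_control)
  if (length(cc) < 2 || length(ct) < 2) {
    warning("condition ", condition, " skipped: <2 usable runs on one side")
    return(NULL)
  }
  sub <- subset_lfq(ds, proteins = proteins, runs = c(cc, ct))
  m <- sub$intensity
  grp <- ifelse(sub$runs$is_control, "ctrl", "sample")
  labels <- classify_missingness(m, grp)
  imp <- impute_mixed(m, labels, grp, strategy_mar = strategy_mar,
                      strategy_mnar = strategy_mnar, k = k, seed = seed)
  res <- moderated_t_matrix(imp[, grp == "sample", drop = FALSE],
                            imp[, grp == "ctrl", drop = FALSE],
                            moderate = moderate)
  out <- data.frame(condition = condition, protein_id = res$protein_id,
                    log_fc = res$log_fc, stat = res$t_mod, p = res$p,
                    p_adj = adjust_bh(res$p), stringsAsFactors = FALSE)
  out$called <- out$p_adj < alpha & out$log_fc > lfc
  out
}

#' Merge technical replicates by the median
#'
#' Per (protein, condition, biological replicate), the merged value is the
#' median over that bio-rep's technical runs, computed over observed values
#' only; an all-missing set stays missing.
#'
#' @param ds an `lfq_dataset` (any scale).
#' @return the dataset with one run per (condition, biological replicate).
#' @export
merge_technical <- function(ds) {
  lab <- condition_of(ds)
  key <- paste(lab, ds$runs$bio_rep, sep = "|")
  uk <- unique(key)
  m <- sapply(uk, function(kk) {
    cols <- key == kk
    apply(ds$intensity[, cols, drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else stats::median(v)
    })
  })
  m <- matrix(m, nrow = nrow(ds$intensity),
              dimnames = list(rownames(ds$intensity), uk))
  first <- match(uk, key)
  runs <- ds$runs[first, , drop = FALSE]
  runs$tech_rep <- 1L
  runs$run_id <- sub("|", "_b", uk, fixed = TRUE)
  colnames(m) <- runs$run_id
  rownames(runs) <- NULL
  lfq_dataset(m, runs, ds$proteins, log2_scale = ds$log2_scale)
}

#' Run the full five-step filter pipeline
#'
#' Applies steps (i)-(v) in their canonical order, log2-transforming after
#' the presence filter, and merges technical replicates for the output
#' dataset. Produces a complete filter report with monotone
#' non-increasing counts.
#'
#' @param ds a raw-scale `lfq_dataset` with bead-control runs.
#' @param params list of parameters; recognized entries (with defaults):
#'   `min_proteins` (NULL), `mad_k` (3), `presence_frac` (0.6),
#'   `alpha` (0.01), `lfc` (1), `strategy_mar` ("knn"),
#'   `strategy_mnar` ("zero_floor"), `k` (10), `moderate` (TRUE),
#'   `seed` (1).
#' @return list: `dataset` (merged log2 dataset), `calls` (per-condition
#'   data.frames from [control_enrichment()]), `interactors` (per-condition
#'   called protein ids), `report` (data.frame of per-step counts),
#'   `removed_runs`.
#' @export
run_filter_pipeline <- function(ds, params = list()) {
  p <- utils::modifyList(list(min_proteins = NULL, mad_k = 3,
                              presence_frac = 0.6, alpha = 0.01, lfc = 1,
                              strategy_mar = "knn",
                              strategy_mnar = "zero_floor", k = 10,
                              moderate = TRUE, seed = 1L), params)
  report <- list()
  note <- function(step, d) {
    report[[length(report) + 1L]] <<- data.frame(
      step = step, n_proteins = nrow(d$intensity), n_runs = ncol(d$intensity),
      n_observations = sum(!is.na(d$intensity) & d$intensity != 0))
  }
  note("input", ds)
  ds <- remove_flagged(ds);            note("remove_flagged", ds)
  ds <- drop_zero_observations(ds);    note("drop_zero", ds)
  out_runs <- detect_outlier_runs(ds, p$min_proteins, p$mad_k)
  if (length(out_runs))
    ds <- subset_lfq(ds, runs = !colnames(ds$intensity) %in% out_runs)
  note("outlier_runs", ds)
  ds <- presence_filter(ds, p$presence_frac)
  keep <- attr(ds, "group_keep")
  note("presence", ds)
  ds <- log2_transform(ds)

  conds <- setdiff(unique(condition_of(ds)), CONTROL_SENTINEL)
  calls <- list()
  for (cl in conds) {
    pr <- if (cl %in% colnames(keep)) rownames(keep)[keep[, cl]] else NULL
    if (is.null(pr) || length(pr) == 0) { calls[[cl]] <- NULL; next }
    calls[[cl]] <- control_enrichment(
      ds, cl, proteins = pr, alpha = p$alpha, lfc = p$lfc,
      strategy_mar = p$strategy_mar, strategy_mnar = p$strategy_mnar,
      k = p$k, moderate = p$moderate, seed = p$seed)
  }
  interactors <- lapply(calls, function(d)
    if (is.null(d)) character() else d$protein_id[d$called])
  merged <- merge_technical(ds)
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  list(dataset = merged, calls = calls, interactors = interactors,
       report = report, removed_runs = out_runs)
}
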