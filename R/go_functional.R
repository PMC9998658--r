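#' @title GO functional analysis
#' @description Both functional-analysis routes over the filtered
#'   interactome: gene set enrichment on a ranked differential result, and
#'   the intensity-collapse route (per-term LFQ sums, factorial ANOVA per
#'   term under collective Hommel correction, Tukey post-hocs under
#'   collective BH), plus Wang semantic similarity with binary-cut
#'   clustering, radar normalization and phenotype correlation.
#' @name go_functional
NULL

# ancestors (including the term itself) for every term, as a named list
term_ancestors <- function(dag) {
  g <- igraph::graph_from_data_frame(dag$edges[c("child", "parent")],
                                     vertices = dag$terms$id, directed = TRUE)
  out <- lapply(dag$terms$id, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))
  names(out) <- dag$terms$id
  out
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is annotated to every ancestor of that term.
#' Idempotent.
#'
#' @param dag a `go_dag`.
#' @param direct data.frame (`gene`, `term`) of direct annotations.
#' @return data.frame (`gene`, `term`) of propagated unique annotations.
#' @export
propagate_annotations <- function(dag, direct) {
  anc <- term_ancestors(dag)
  reps <- lengths(anc[direct$term])
  out <- data.frame(gene = rep(direct$gene, reps),
                    term = unlist(anc[direct$term], use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse protein intensities onto GO terms
#'
#' For each term and each sample, sums the raw-scale LFQ intensities of all
#' identified proteins annotated to the term (a protein missing in a sample
#' contributes 0; a protein in k terms contributes to all k). Terms with no
#' identified protein are absent from the result.
#'
#' @param ds an `lfq_dataset` (typically merged over technical replicates);
#'   log2 data are converted back to the raw scale for summing.
#' @param annotations data.frame (`gene`, `term`), usually propagated;
#'   genes matched against `ds$proteins$gene_name`.
#' @return terms x samples matrix; the number of contributing proteins per
#'   term is in the `"n_proteins"` attribute.
#' @export
collapse_to_terms <- function(ds, annotations) {
  m <- ds$intensity
  if (ds$log2_scale) m <- 2 ^ m
  m[is.na(m)] <- 0
  ann <- annotations[annotations$gene %in% ds$proteins$gene_name, , drop = FALSE]
  if (!nrow(ann)) stop("no annotation matches an identified protein")
  terms <- sort(unique(ann$term))
  ridx <- match(ann$gene, ds$proteins$gene_name)
  inc <- matrix(0, length(terms), nrow(m),
                dimnames = list(terms, rownames(m)))
  inc[cbind(match(ann$term, terms), ridx)] <- 1
  tim <- inc %*% m
  attr(tim, "n_proteins") <- rowSums(inc)
  tim
}

#' Per-term factorial ANOVA scan with collective Hommel correction
#'
#' Runs a factorial ANOVA ([factorial_anova()]) on every term's (log2)
#' summed intensities, collects all term-by-effect p-values, adjusts them
#' collectively with Hommel's procedure, then computes Tukey HSD tables for
#' the main-effect factors of terms with any adjusted p below `alpha`; all
#' Tukey p-values are then collectively BH-adjusted.
#'
#' @param tim terms x samples matrix from [collapse_to_terms()].
#' @param design data.frame of per-sample factors (rows match columns of
#'   `tim`).
#' @param factors factor columns of `design` to use.
#' @param alpha significance level on the Hommel-adjusted p (default 0.05).
#' @param min_proteins terms with fewer annotated identified proteins are
#'   excluded (default 3), using the `"n_proteins"` attribute when present.
#' @param log2 scan log2(1 + sum) rather than the raw sum (default TRUE;
#'   term sums are sums of log-normals, so factor effects are closer to
#'   additive on the log scale).
#' @return list: `anova` (data.frame `term`, `effect`, `sum_sq`, `df`, `F`,
#'   `p`, `p_hommel`), `tukey` (data.frame of post-hoc comparisons with
#'   collectively BH-adjusted `p_adj`), `excluded_terms`.
#' @export
term_anova_scan <- function(tim, design, factors = names(design),
                            alpha = 0.05, min_proteins = 3, log2 = TRUE) {
  np <- attr(tim, "n_proteins")
  excluded <- character()
  if (!is.null(np)) {
    excluded <- rownames(tim)[np < min_proteins]
    tim <- tim[np >= min_proteins, , drop = FALSE]
  }
  if (!nrow(tim)) stop("no term left to scan")
  rows <- list(); fits <- list()
  for (t in rownames(tim)) {
    y <- as.numeric(tim[t, ])
    if (log2) y <- base::log2(1 + y)
    if (stats::var(y) < 1e-12) next  # constant term: nothing to test
    fit <- try(factorial_anova(y, design, factors), silent = TRUE)
    if (inherits(fit, "try-error")) next
    fits[[t]] <- fit
    rows[[t]] <- data.frame(term = t, effect = fit$term, sum_sq = fit$sum_sq,
                            df = fit$df, F = fit$F, p = fit$p,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(anova = NULL, tukey = NULL, excluded_terms = excluded))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$p)
  tab$p_hommel <- NA_real_
  tab$p_hommel[ok] <- adjust_hommel(tab$p[ok])

  sig <- unique(tab$term[!is.na(tab$p_hommel) & tab$p_hommel < alpha])
  tuk <- list()
  for (t in sig) {
    fit <- fits[[t]]
    for (f in attr(fit, "factors")) {
      tt <- tukey_hsd(fit, f)
      tt$p_adj <- NULL
      tuk[[length(tuk) + 1L]] <- cbind(term = t, factor = f, tt,
                                       stringsAsFactors = FALSE)
    }
  }
  tukey <- if (length(tuk)) do.call(rbind, tuk) else NULL
  if (!is.null(tukey)) {
    tukey$p_adj <- adjust_bh(tukey$p)
    rownames(tukey) <- NULL
  }
  list(anova = tab, tukey = tukey, excluded_terms = excluded)
}

#' Gene set enrichment analysis (weighted running-sum statistic)
#'
#' The classical weighted Kolmogorov-Smirnov-like statistic: walking down
#' the ranking, the running sum gains |score|^`weight` (normalized) at
#' set members and loses 1/(N - set size) at non-members; the enrichment
#' score ES is the signed maximum deviation. The null is gene-label
#' permutation: random sets of the same size. The returned permutation p is
#' (1 + #\{|ES_perm| >= |ES|\}) / (n_perm + 1).
#'
#' @param ranked named numeric vector of per-gene scores (sorted internally,
#'   decreasing).
#' @param gene_set character vector of set members.
#' @param weight exponent on |score| (default 1; 0 gives the unweighted KS).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `es`, `nes`, `p_perm`, `leading_edge`.
#' @export
gsea <- function(ranked, gene_set, weight = 1, n_perm = 1000, seed = 1L) {
  ranked <- sort(ranked, decreasing = TRUE)
  genes <- names(ranked)
  N <- length(genes)
  in_set <- genes %in% gene_set
  ns <- sum(in_set)
  if (ns == 0) stop("gene set has no member in the ranking")
  if (ns == N) return(list(es = 0, nes = 0, p_perm = 1,
                           leading_edge = character()))
  es_of <- function(hit) {
    w <- abs(ranked) ^ weight
    inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - sum(hit)))
    run <- cumsum(inc)
    i <- which.max(abs(run))
    list(es = run[i], at = i)
  }
  obs <- es_of(in_set)
  perm <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_of(sample(in_set))$es
    }, numeric(1))
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs$es))) / (n_perm + 1)
  denom <- mean(abs(perm))
  nes <- if (denom > 0) obs$es / denom else 0
  le <- if (obs$es >= 0) genes[seq_len(obs$at)][in_set[seq_len(obs$at)]]
        else genes[obs$at:N][in_set[obs$at:N]]
  list(es = obs$es, nes = nes, p_perm = p_perm, leading_edge = le)
}

#' GSEA over many gene sets with BH-adjusted permutation p-values
#'
#' @param ranked named numeric score vector.
#' @param gene_sets named list of character vectors.
#' @param min_size,max_size set-size bounds; sets outside are skipped.
#' @inheritParams gsea
#' @return data.frame: `term`, `size`, `es`, `nes`, `p_perm`, `fdr`.
#' @export
gsea_scan <- function(ranked, gene_sets, weight = 1, n_perm = 1000,
                      seed = 1L, min_size = 3,
                      max_size = length(ranked) - 3) {
  rows <- list()
  for (nm in names(gene_sets)) {
    sz <- sum(names(ranked) %in% gene_sets[[nm]])
    if (sz < min_size || sz > max_size) next
    r <- gsea(ranked, gene_sets[[nm]], weight = weight, n_perm = n_perm,
              seed = seed + match(nm, names(gene_sets)))
    rows[[nm]] <- data.frame(term = nm, size = sz, es = r$es, nes = r$nes,
                             p_perm = r$p_perm, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no gene set within the size bounds")
  out <- do.call(rbind, rows)
  out$fdr <- adjust_bh(out$p_perm)
  rownames(out) <- NULL
  out
}

## ---- semantic similarity -----------------------------------------------

# Wang S-value table for one term: named vector over the term's ancestor
# closure, S(term) = 1, S(parent) = max over paths of the product of edge
# weights.
wang_svalues <- function(dag, term, w_is_a = 0.8, w_part_of = 0.6) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  e <- dag$edges
  wts <- ifelse(e$type == "part_of", w_part_of, w_is_a)
  s <- stats::setNames(0, term)
  s[term] <- 1
  repeat {
    changed <- FALSE
    hit <- e$child %in% names(s)
    for (i in which(hit)) {
      cand <- wts[i] * s[[e$child[i]]]
      cur <- if (e$parent[i] %in% names(s)) s[[e$parent[i]]] else 0
      if (cand > cur + 1e-15) { s[e$parent[i]] <- cand; changed <- TRUE }
    }
    if (!changed) break
  }
  s
}

#' Wang graph-based semantic similarity of two GO terms
#'
#' Each term's ancestor closure gets S-values: 1 at the term itself, and
#' for an ancestor the maximum over paths of the product of edge weights
#' (`is_a` 0.8, `part_of` 0.6). The similarity is the sum of both terms'
#' S-values over their common ancestors, divided by the sum of all S-values
#' of both terms. Symmetric, in \[0, 1\], and 1 for identical terms.
#'
#' @param dag a `go_dag`.
#' @param term1,term2 term ids.
#' @param w_is_a,w_part_of edge weights.
#' @return similarity in \[0, 1\].
#' @export
wang_similarity <- function(dag, term1, term2, w_is_a = 0.8, w_part_of = 0.6) {
  s1 <- wang_svalues(dag, term1, w_is_a, w_part_of)
  s2 <- wang_svalues(dag, term2, w_is_a, w_part_of)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Pairwise Wang similarity matrix
#'
#' @param dag a `go_dag`.
#' @param terms term ids (default all).
#' @inheritParams wang_similarity
#' @return symmetric matrix with unit diagonal.
#' @export
wang_similarity_matrix <- function(dag, terms = dag$terms$id,
                                   w_is_a = 0.8, w_part_of = 0.6) {
  sv <- lapply(terms, wang_svalues, dag = dag, w_is_a = w_is_a,
               w_part_of = w_part_of)
  n <- length(terms)
  sim <- diag(1, n)
  dimnames(sim) <- list(terms, terms)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    common <- intersect(names(sv[[i]]), names(sv[[j]]))
    sim[i, j] <- sim[j, i] <-
      sum(sv[[i]][common] + sv[[j]][common]) / (sum(sv[[i]]) + sum(sv[[j]]))
  }
  sim
}

#' Binary-cut clustering of a similarity matrix
#'
#' Recursive two-way partitioning: if the current term set is cohesive --
#' its mean off-diagonal similarity is at least `cut_score_threshold` -- it
#' becomes one cluster; otherwise it is split in two by average-linkage
#' hierarchical clustering on 1 - similarity and both halves are processed
#' recursively. Deterministic. Singletons are always clusters.
#'
#' @param sim symmetric similarity matrix in \[0, 1\] with unit diagonal.
#' @param cut_score_threshold cohesion threshold (default 0.85).
#' @return list: `similarity`, `labels` (named integer vector),
#'   `sizes` (table of cluster sizes).
#' @export
binary_cut_cluster <- function(sim, cut_score_threshold = 0.85) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix not symmetric")
  n <- nrow(sim)
  ids <- rownames(sim) %||% as.character(seq_len(n))
  labels <- stats::setNames(integer(n), ids)
  next_id <- 0L
  assign_cluster <- function(idx) {
    next_id <<- next_id + 1L
    labels[idx] <<- next_id
  }
  recurse <- function(idx) {
    if (length(idx) == 1L) { assign_cluster(idx); return(invisible()) }
    sub <- sim[idx, idx, drop = FALSE]
    coh <- mean(sub[upper.tri(sub)])
    if (coh >= cut_score_threshold) { assign_cluster(idx); return(invisible()) }
    hc <- stats::hclust(stats::as.dist(1 - sub), method = "average")
    grp <- stats::cutree(hc, k = 2)
    recurse(idx[grp == 1]); recurse(idx[grp == 2])
  }
  recurse(seq_len(n))
  list(similarity = sim, labels = labels,
       sizes = table(labels))
}

#' Radar normalization of an LS-means table
#'
#' Each parameter (row) is divided by its own maximum so values lie in
#' \[0, 1\] with the maximal cell at 1. Negative entries are outside the
#' defined domain and raise an error; an all-zero row is returned unchanged.
#'
#' @param ls_means numeric matrix or data.frame, parameters x groups.
#' @return the normalized matrix, same dimnames and order.
#' @export
radar_normalize <- function(ls_means) {
  m <- as.matrix(ls_means)
  if (any(m < 0, na.rm = TRUE)) stop("negative entries are out of domain")
  mx <- apply(m, 1, max, na.rm = TRUE)
  sweep_rows <- ifelse(mx > 0, mx, 1)
  m / sweep_rows
}

#' Pearson correlation of phenotypic parameters vs term intensity sums
#'
#' @param pheno parameters x groups matrix.
#' @param term_sums terms x groups matrix; columns are matched to `pheno`
#'   by name.
#' @return parameters x terms matrix of Pearson r in \[-1, 1\].
#' @export
phenotype_correlation <- function(pheno, term_sums) {
  pheno <- as.matrix(pheno); term_sums <- as.matrix(term_sums)
  common <- intersect(colnames(pheno), colnames(term_sums))
  if (length(common) < 3) stop("need >= 3 matched groups")
  stats::cor(t(pheno[, common, drop = FALSE]),
             t(term_sums[, common, drop = FALSE]), method = "pearson")
}
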