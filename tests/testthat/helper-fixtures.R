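# Fixture builders and brute-force oracles shared across the suite.

# tiny LFQ dataset with explicit values; runs split into one condition and
# a bead-control group
toy_lfq <- function(m, n_bio = NULL, n_ctrl = 0, genetic = "G12D",
                    culture = "IL6", conc = "20") {
  n_run <- ncol(m)
  n_smp <- n_run - n_ctrl
  runs <- data.frame(
    run_id = paste0("r", seq_len(n_run)),
    genetic_context = c(rep(genetic, n_smp), rep("ctrl", n_ctrl)),
    culture_context = c(rep(culture, n_smp), rep("ctrl", n_ctrl)),
    concentration = c(rep(conc, n_smp), rep("ctrl", n_ctrl)),
    bio_rep = c(if (is.null(n_bio)) seq_len(n_smp) else n_bio,
                seq_len(max(n_ctrl, 0)))[seq_len(n_run)],
    tech_rep = 1L,
    is_control = c(rep(FALSE, n_smp), rep(TRUE, n_ctrl)),
    stringsAsFactors = FALSE)
  # distinct tech reps when bio reps repeat
  key <- paste(runs$genetic_context, runs$bio_rep, runs$is_control)
  runs$tech_rep <- stats::ave(seq_len(n_run), key, FUN = seq_along)
  proteins <- data.frame(
    protein_id = paste0("P", seq_len(nrow(m))),
    gene_name = paste0("G", seq_len(nrow(m))),
    flag_site_only = FALSE, flag_contaminant = FALSE, flag_reverse = FALSE,
    stringsAsFactors = FALSE)
  lfq_dataset(m, runs, proteins)
}

# brute-force BH: adjusted p_i = min over j with p_j >= p_i of n*p_(j)/rank_j
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n * ranked[i:n] / (i:n)))
  }
  adj[order(o)]
}

# brute-force Hommel: closed testing over all subsets with Simes local tests
brute_hommel <- function(p) {
  n <- length(p)
  idx <- seq_len(n)
  adj <- numeric(n)
  subsets <- unlist(lapply(idx, function(k) utils::combn(idx, k, simplify = FALSE)),
                    recursive = FALSE)
  simes <- function(ps) {
    ps <- sort(ps)
    min(length(ps) * ps / seq_along(ps))
  }
  for (i in idx) {
    adj[i] <- min(1, max(vapply(subsets, function(S)
      if (i %in% S) simes(p[S]) else -Inf, numeric(1))))
  }
  adj
}

# brute-force ancestor closure by repeated parent lookup
brute_ancestors <- function(dag, term) {
  anc <- term
  repeat {
    parents <- dag$edges$parent[dag$edges$child %in% anc]
    new <- setdiff(parents, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  sort(anc)
}

# brute-force Wang S-values: enumerate every upward path, S = max product
brute_wang_svalues <- function(dag, term, w_is_a = 0.8, w_part_of = 0.6) {
  s <- new.env(parent = emptyenv())
  assign(term, 1, envir = s)
  walk <- function(node, value) {
    e <- dag$edges[dag$edges$child == node, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      w <- if (e$type[i] == "part_of") w_part_of else w_is_a
      v <- value * w
      p <- e$parent[i]
      old <- if (exists(p, envir = s)) get(p, envir = s) else 0
      if (v > old) assign(p, v, envir = s)
      walk(p, v)
    }
  }
  walk(term, 1)
  vals <- mget(ls(s), envir = s)
  stats::setNames(as.numeric(vals), names(vals))
}

brute_wang_similarity <- function(dag, t1, t2, w_is_a = 0.8, w_part_of = 0.6) {
  s1 <- brute_wang_svalues(dag, t1, w_is_a, w_part_of)
  s2 <- brute_wang_svalues(dag, t2, w_is_a, w_part_of)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# a small hand-drawable toy network: KRAS -> {A,B}; A-B-C-D diamond to E
toy_network <- function() {
  edges <- data.frame(node_a = c("A", "A", "B", "B", "C", "D"),
                      node_b = c("B", "C", "C", "D", "D", "E"),
                      score = 0.9, stringsAsFactors = FALSE)
  build_network(edges, effectors = c("A", "B"), source = "KRAS")
}
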