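# 5-term fixture: root <- mid <- {leaf1, leaf2}; side <- root (part_of)
fixture_dag <- function() {
  terms <- data.frame(id = c("root", "mid", "leaf1", "leaf2", "side"),
                      name = letters[1:5], namespace = "biological_process")
  edges <- data.frame(
    child = c("mid", "leaf1", "leaf2", "side"),
    parent = c("root", "mid", "mid", "root"),
    type = c("is_a", "is_a", "is_a", "part_of"))
  go_dag(terms, edges)
}

test_that("annotation propagation follows the true-path rule and is idempotent", {
  dag <- fixture_dag()
  direct <- data.frame(gene = c("g1", "g2"), term = c("leaf1", "side"))
  prop <- propagate_annotations(dag, direct)
  expect_setequal(prop$term[prop$gene == "g1"], c("leaf1", "mid", "root"))
  expect_setequal(prop$term[prop$gene == "g2"], c("side", "root"))
  expect_identical(propagate_annotations(dag, prop), prop)
  # matches the brute-force ancestor closure on a generated 20-term DAG
  gg <- simulate_go(20, 4, genes = "g1", seed = 21)
  t0 <- gg$annotations$term[1]
  prop2 <- propagate_annotations(gg$dag, gg$annotations[1, ])
  expect_setequal(prop2$term, brute_ancestors(gg$dag, t0))
})

test_that("term collapse sums identified-protein intensities per sample", {
  m <- matrix(c(5, 7, 11,
                NA, 2, 3), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  ds <- toy_lfq(m[, , drop = FALSE])
  ann <- data.frame(gene = c("G1", "G2", "G2", "G3"),
                    term = c("T1", "T1", "T2", "T2"))
  tim <- collapse_to_terms(ds, ann)
  expect_equal(tim["T1", "r1"], 5 + 7)       # A=5, B=7 -> 12
  expect_equal(tim["T2", "r1"], 7 + 11)      # shared protein counts in both
  expect_equal(tim["T1", "r2"], 0 + 2)       # missing contributes 0
  expect_equal(attr(tim, "n_proteins"), c(T1 = 2, T2 = 2))
})

test_that("the term ANOVA scan finds planted effects and spares null terms", {
  # direct check on a hand-built term matrix: term T1 shifted by factor A
  set.seed(31)
  design <- expand.grid(A = c("a", "b"), B = c("x", "y"), rep = 1:3)[, 1:2]
  n <- nrow(design)
  tim <- rbind(T1 = 2^(10 + rnorm(n, 0, 0.2) + 2 * (design$A == "b")),
               T2 = 2^(10 + rnorm(n, 0, 0.2)),
               T3 = 2^(10 + rnorm(n, 0, 0.2)))
  scan <- term_anova_scan(tim, design, c("A", "B"), min_proteins = 0)
  a1 <- scan$anova[scan$anova$term == "T1" & scan$anova$effect == "A", ]
  expect_lt(a1$p_hommel, 0.05)
  null_p <- scan$anova$p_hommel[scan$anova$term != "T1"]
  expect_true(all(null_p > 0.05))
  # Tukey tables only for significant terms, BH applied collectively
  expect_true(all(scan$tukey$term == "T1"))
  expect_true(all(scan$tukey$p_adj >= scan$tukey$p - 1e-15))
  # all-constant matrix -> nothing to test
  timc <- matrix(5, 2, n, dimnames = list(c("T1", "T2"), NULL))
  scanc <- term_anova_scan(timc, design, c("A", "B"), min_proteins = 0)
  expect_null(scanc$anova)
})

test_that("Hommel on a single term's p-vector is a per-family identity", {
  set.seed(33)
  design <- expand.grid(A = c("a", "b"), B = c("x", "y"), rep = 1:3)[, 1:2]
  n <- nrow(design)
  tim <- rbind(T1 = 2^(10 + rnorm(n, 0, 0.3)))
  scan <- term_anova_scan(tim, design, c("A", "B"), min_proteins = 0)
  expect_equal(scan$anova$p_hommel, adjust_hommel(scan$anova$p))
})

test_that("GSEA scores behave at the extremes and under the KS sign property", {
  set.seed(37)
  r <- setNames(sort(rnorm(60), decreasing = TRUE), paste0("g", 1:60))
  # set = top of the ranking -> near-maximal ES
  top <- gsea(r, names(r)[1:10], n_perm = 200, seed = 2)
  expect_gt(top$es, 0.9)
  expect_lt(top$p_perm, 0.05)
  # set = the whole list -> degenerate ES of 0
  expect_equal(gsea(r, names(r))$es, 0)
  # unweighted ES of a set and its complement have opposite signs
  for (i in 1:10) {
    rr <- setNames(rnorm(40), paste0("x", 1:40))
    s <- sample(names(rr), 15)
    e1 <- gsea(rr, s, weight = 0, n_perm = 10, seed = i)$es
    e2 <- gsea(rr, setdiff(names(rr), s), weight = 0, n_perm = 10, seed = i)$es
    expect_lte(e1 * e2, 0)
  }
})

test_that("GSEA permutation p-values are calibrated under the null", {
  set.seed(41)
  ps <- vapply(1:200, function(i) {
    r <- setNames(rnorm(40), paste0("g", 1:40))
    gsea(r, sample(names(r), 8), n_perm = 99, seed = i)$p_perm
  }, numeric(1))
  # roughly uniform: mean near 0.5, not enriched at small values
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("Wang similarity matches hand-computed and brute-force S-values", {
  dag <- fixture_dag()
  # hand calculation: S_mid = {mid:1, root:0.8} SV = 1.8
  #                   S_leaf1 = {leaf1:1, mid:0.8, root:0.64} SV = 2.44
  # common {mid, root}: (1+0.8) + (0.8+0.64) = 3.24; 3.24/4.24 = 0.7642
  expect_equal(wang_similarity(dag, "leaf1", "mid"), 3.24 / 4.24,
               tolerance = 1e-4)
  # part_of weight: S_side = {side:1, root:0.6}; vs mid common {root}:
  # (0.6+0.8)/(1.6+1.8) = 0.4118
  expect_equal(wang_similarity(dag, "side", "mid"), 1.4 / 3.4,
               tolerance = 1e-4)
  expect_equal(wang_similarity(dag, "leaf2", "leaf2"), 1)
  # brute-force equivalence on random DAGs of up to 12 terms
  for (s in 1:5) {
    gg <- simulate_go(sample(5:12, 1), 4, genes = "g", seed = s)
    ids <- gg$dag$terms$id
    pairs <- utils::combn(sample(ids, min(5, length(ids))), 2)
    for (j in seq_len(ncol(pairs))) {
      expect_equal(wang_similarity(gg$dag, pairs[1, j], pairs[2, j]),
                   brute_wang_similarity(gg$dag, pairs[1, j], pairs[2, j]),
                   tolerance = 1e-12)
    }
  }
  # deep chain: terms sharing only the root have similarity near 0
  n <- 12
  terms <- data.frame(id = c("r", paste0("a", 1:n), paste0("b", 1:n)),
                      name = "x", namespace = "biological_process")
  edges <- data.frame(
    child = c("a1", paste0("a", 2:n), "b1", paste0("b", 2:n)),
    parent = c("r", paste0("a", 1:(n - 1)), "r", paste0("b", 1:(n - 1))),
    type = "is_a")
  deep <- go_dag(terms, edges)
  expect_lt(wang_similarity(deep, paste0("a", n), paste0("b", n)), 0.05)
})

test_that("binary cut separates blocks, isolates singletons, and responds to the threshold", {
  bl <- matrix(0, 6, 6); bl[1:3, 1:3] <- 1; bl[4:6, 4:6] <- 1; diag(bl) <- 1
  rownames(bl) <- colnames(bl) <- paste0("t", 1:6)
  cl <- binary_cut_cluster(bl)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(unname(cl$labels[1]), unname(cl$labels[2]))
  expect_false(cl$labels[1] == cl$labels[4])
  # identity matrix -> all singletons
  cli <- binary_cut_cluster(diag(1, 5))
  expect_equal(length(unique(cli$labels)), 5)
  # a higher cohesion bar can only split more: cluster count is
  # non-decreasing in the threshold
  set.seed(43)
  base <- matrix(runif(64, 0.3, 0.9), 8, 8)
  sim <- (base + t(base)) / 2; diag(sim) <- 1
  counts <- vapply(c(0.3, 0.5, 0.7, 0.85, 0.95), function(th)
    length(unique(binary_cut_cluster(sim, th)$labels)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("radar normalization and phenotype correlation follow their formulas", {
  m <- rbind(p1 = c(2, 4, 8), p2 = c(3, 3, 3))
  rn <- radar_normalize(m)
  expect_equal(unname(rn["p1", ]), c(0.25, 0.5, 1))
  expect_equal(unname(rn["p2", ]), c(1, 1, 1))
  expect_error(radar_normalize(rbind(c(-1, 2))), "domain")

  ph <- rbind(par = c(1, 2, 4))
  ts <- rbind(t1 = c(2, 4, 8), t2 = c(-1, -2, -4), t3 = c(5, 1, 3))
  colnames(ph) <- colnames(ts) <- c("g1", "g2", "g3")
  r <- phenotype_correlation(ph, ts)
  expect_equal(r["par", "t1"], 1)
  expect_equal(r["par", "t2"], -1)
  # closed form on the 3-point example
  expect_equal(r["par", "t3"], cor(c(1, 2, 4), c(5, 1, 3)))
})
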