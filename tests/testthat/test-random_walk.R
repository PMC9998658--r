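test_that("network construction filters scores strictly below threshold and far nodes", {
  edges <- data.frame(node_a = c("A", "A", "B", "C", "D", "E"),
                      node_b = c("B", "C", "C", "D", "E", "F"),
                      score = c(0.70, 0.69, 0.9, 0.9, 0.9, 0.9))
  net <- build_network(edges, effectors = "A", source = "S", max_sp = 4)
  # 0.69 edge absent, 0.70 edge kept
  expect_false(any(net$edges$node_a == "A" & net$edges$node_b == "C"))
  expect_true(any(net$edges$node_a == "A" & net$edges$node_b == "B"))
  # F is 5 hops from the effector A (A-B-C-D-E-F) -> excluded
  expect_false("F" %in% net$nodes)
  expect_true("E" %in% net$nodes)
  # an isolated effector is kept with a warning
  edges2 <- data.frame(node_a = c("A", "C"), node_b = c("B", "D"),
                       score = c(0.5, 0.9))
  expect_warning(net2 <- build_network(edges2, effectors = c("A", "C"),
                                       source = "S"), "isolated")
  expect_true("A" %in% net2$nodes)
})

test_that("the step distribution implements the 20-fold evidence bias", {
  net <- toy_network()
  # neighbours of C: {A, B, D}; evidence {B, D} -> (1/41, 20/41, 20/41)
  p <- step_distribution(net, "C", evidence = c("B", "D"))
  expect_equal(unname(p[c("B", "D", "A")]), c(20 / 41, 20 / 41, 1 / 41))
  # one in / one out -> (20/21, 1/21)
  p2 <- step_distribution(net, "A", evidence = "B")  # neighbours {B, C}
  expect_equal(unname(p2[c("B", "C")]), c(20 / 21, 1 / 21))
  # one of three in evidence -> (20/22, 1/22, 1/22)
  p2b <- step_distribution(net, "D", evidence = "E")  # neighbours {B, C, E}
  expect_equal(unname(p2b[c("E", "B", "C")]), c(20 / 22, 1 / 22, 1 / 22))
  # no neighbour in evidence -> uniform; always sums to 1
  p3 <- step_distribution(net, "C", evidence = character())
  expect_equal(unname(p3), rep(1 / 3, 3))
  for (nd in c("A", "B", "C", "D", "KRAS"))
    expect_equal(sum(step_distribution(net, nd, c("B"))), 1)
})

test_that("randomized neighbourhoods match the weight-normalization oracle", {
  set.seed(47)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    nbs <- paste0("n", seq_len(k))
    edges <- data.frame(node_a = "hub", node_b = nbs, score = 0.9)
    net <- build_network(edges, effectors = "n1", source = "S")
    ev <- nbs[runif(k) < 0.5]
    bf <- sample(c(1, 5, 20, 100), 1)
    p <- step_distribution(net, "hub", ev, bias_factor = bf)
    w <- ifelse(nbs %in% ev, bf, 1)
    expect_equal(unname(p[nbs]), w / sum(w), tolerance = 1e-12)
  }
})

test_that("walk length is shortest path plus two, with directed source edges", {
  net <- toy_network()
  expect_equal(walk_length(net, "A"), 3)   # sp 1 (effector)
  expect_equal(walk_length(net, "C"), 4)   # KRAS->A/B->C, sp 2
  expect_equal(walk_length(net, "E"), 5)   # KRAS->B->D->E, sp 3
  edges <- data.frame(node_a = "A", node_b = "B", score = 0.9)
  net2 <- build_network(edges, effectors = "A", source = "S")
  expect_error(walk_length(net2, "Q"), "not in network")
  # an effector outside the edge-list universe is rejected outright
  expect_error(build_network(edges, effectors = c("A", "Z"), source = "S"),
               "universe")
})

test_that("forced walks always succeed and runs are seed-reproducible", {
  # source -> single effector A -> target B: every step is forced
  edges <- data.frame(node_a = "A", node_b = "B", score = 0.9)
  net <- build_network(edges, effectors = "A", source = "S")
  pe <- run_walks(net, walk_spec("B", n_walks = 500, seed = 3))
  expect_equal(pe$n_success, 500)
  expect_equal(pe$paths$path, "S->A->B")
  expect_error(run_walks(net, walk_spec("S", n_walks = 10)), "source")
  net5 <- toy_network()
  s <- walk_spec("E", n_walks = 5000, evidence = "D", seed = 11)
  expect_identical(run_walks(net5, s)$paths, run_walks(net5, s)$paths)
})

test_that("exact enumeration matches a hand expansion and conserves probability", {
  # triangle: S -> A (effector); A-B, A-C, B-C; target B, walklen 4
  edges <- data.frame(node_a = c("A", "A", "B"), node_b = c("B", "C", "C"),
                      score = 0.9)
  net <- build_network(edges, effectors = "A", source = "S")
  spec <- walk_spec("B", n_walks = 1)
  ex <- enumerate_paths_exact(net, spec)
  expect_equal(ex$walklen, 4)
  got <- setNames(ex$paths$prob, ex$paths$path)
  expect_equal(unname(got["S->A->B"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(got["S->A->C->B"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(got["S->A->C->A->B"]), 0.125, tolerance = 1e-12)
  expect_equal(ex$p_success + ex$p_fail, 1, tolerance = 1e-12)
  expect_equal(ex$p_success, 0.875, tolerance = 1e-12)
  # forced-path graph: single path with probability 1
  e2 <- data.frame(node_a = "A", node_b = "B", score = 0.9)
  n2 <- build_network(e2, effectors = "A", source = "S")
  ex2 <- enumerate_paths_exact(n2, walk_spec("B", n_walks = 1))
  expect_equal(ex2$paths$prob, 1, tolerance = 1e-12)
})

test_that("empirical frequencies converge to the exact distribution", {
  net <- toy_network()
  spec <- walk_spec("E", n_walks = 100000, evidence = c("B", "D"), seed = 5)
  ex <- enumerate_paths_exact(net, spec)
  pe <- run_walks(net, spec)
  m <- merge(pe$paths, ex$paths, by = "path", all = TRUE)
  m$freq[is.na(m$freq)] <- 0; m$prob[is.na(m$prob)] <- 0
  se <- sqrt(m$prob * (1 - m$prob) / spec$n_walks)
  expect_true(all(abs(m$freq - m$prob) <= 3.5 * pmax(se, 1e-9) + 1e-6))
  tv <- 0.5 * (sum(abs(m$freq - m$prob)) +
                 abs(pe$n_success / spec$n_walks - ex$p_success))
  expect_lt(tv, 0.01)
})

test_that("an unbiased walk on a symmetric graph gives symmetric path probabilities", {
  # two mirror-image routes A->C and B->C; bias 1 must treat them equally
  edges <- data.frame(node_a = c("A", "B"), node_b = c("C", "C"), score = 0.9)
  net <- build_network(edges, effectors = c("A", "B"), source = "S")
  ex <- enumerate_paths_exact(net, walk_spec("C", n_walks = 1,
                                             bias_factor = 1))
  p <- setNames(ex$paths$prob, ex$paths$path)
  expect_equal(unname(p["S->A->C"]), unname(p["S->B->C"]), tolerance = 1e-12)
})

test_that("bias monotonically favours evidence-interior paths (exact oracle)", {
  net <- toy_network()
  # interior nodes of KRAS->B->D->E plus the target itself: the bias can
  # only help evidence-interior routes when the absorbing end is not
  # penalized relative to its biased competitors
  ev <- c("B", "D", "E")
  mass <- vapply(c(1, 5, 20, 100), function(bf) {
    ex <- enumerate_paths_exact(net, walk_spec("E", n_walks = 1,
                                               bias_factor = bf,
                                               evidence = ev))
    keep <- vapply(strsplit(ex$paths$path, "->", fixed = TRUE), function(nd)
      all(nd[-c(1, length(nd))] %in% ev), logical(1))
    sum(ex$paths$prob[keep])
  }, numeric(1))
  expect_true(all(diff(mass) >= -1e-12))
})

test_that("path filtering applies the frequency cut, top-k and tie rules", {
  pe <- structure(list(paths = data.frame(
    path = c("S->A->T", "S->B->T", "S->C->D->T", "S->B->C->T", "S->E->T"),
    count = c(500, 300, 300, 200, 1),
    freq = c(500, 300, 300, 200, 1) / 1e6), n_walks = 1e6,
    n_success = 1301, target = "T", walklen = 4), class = "path_ensemble")
  r <- filter_and_rank_paths(pe, min_freq = 1e-5, k = 3)
  expect_equal(nrow(r), 3)
  expect_false("S->E->T" %in% r$path)          # 1e-6 < threshold
  # tie at 300: the shorter path ranks first
  expect_equal(r$path[2], "S->B->T")
  expect_equal(r$path[3], "S->C->D->T")
  r10 <- filter_and_rank_paths(pe, min_freq = 1e-7, k = 10)
  expect_equal(nrow(r10), 5)
})

test_that("condition networks and effector traversal aggregate path weights", {
  rp <- data.frame(path = c("S->A->B->T", "S->A->C->T"),
                   freq = c(0.3, 0.1))
  cn <- condition_network(rp)
  expect_equal(cn$weight[cn$from == "S" & cn$to == "A"], 0.4)  # shared edge
  expect_equal(cn$weight[cn$from == "B" & cn$to == "T"], 0.3)
  tv <- effector_traversal(rp, effectors = c("A", "B", "Z"))
  expect_equal(unname(tv), c(0.4, 0.3, 0))
  tc <- effector_traversal(rp, effectors = c("A", "B", "Z"), mode = "count")
  expect_equal(unname(tc), c(2, 1, 0))
  # evidence sets that differ push traversal toward the biased effector
  net <- toy_network()
  rank_for <- function(ev) {
    pe <- run_walks(net, walk_spec("E", n_walks = 20000, evidence = ev,
                                   seed = 7))
    filter_and_rank_paths(pe)
  }
  etm <- effector_traversal_matrix(
    list(condA = rank_for(c("A", "C")), condB = rank_for(c("B", "D"))),
    effectors = net$effectors)
  expect_gt(etm["B", "condB"], etm["B", "condA"])
})

test_that("all walk outputs are invariant under node relabelling", {
  edges <- data.frame(node_a = c("A", "A", "B", "C"),
                      node_b = c("B", "C", "C", "D"), score = 0.9)
  relab <- c(A = "W", B = "X", C = "Y", D = "Z")
  edges2 <- data.frame(node_a = unname(relab[edges$node_a]),
                       node_b = unname(relab[edges$node_b]), score = 0.9)
  n1 <- build_network(edges, effectors = "A", source = "S")
  n2 <- build_network(edges2, effectors = "W", source = "S")
  e1 <- enumerate_paths_exact(n1, walk_spec("D", n_walks = 1, evidence = "B"))
  e2 <- enumerate_paths_exact(n2, walk_spec("Z", n_walks = 1, evidence = "X"))
  rename <- function(p) {
    for (nm in names(relab)) p <- gsub(paste0("\\b", nm, "\\b"), relab[nm], p)
    p
  }
  expect_equal(setNames(e2$paths$prob, e2$paths$path),
               setNames(e1$paths$prob, rename(e1$paths$path)))
})
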