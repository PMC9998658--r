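test_that("missingness classification follows the group-wise rule", {
  m <- matrix(1, 3, 6, dimnames = list(paste0("P", 1:3), paste0("r", 1:6)))
  groups <- rep(c("A", "B"), each = 3)
  m[1, 1:3] <- NA            # all missing in A, observed in B -> MNAR in A
  m[2, 1:2] <- NA            # 2 of 3 missing in A -> MAR
  lab <- classify_missingness(m, groups)
  expect_equal(lab["P1", "A"], "MNAR")
  expect_equal(lab["P1", "B"], "complete")
  expect_equal(lab["P2", "A"], "MAR")
  expect_equal(lab["P3", "A"], "complete")
})

test_that("imputation strategies fill as specified and leave observed cells alone", {
  set.seed(3)
  m <- matrix(rnorm(50 * 8, 20, 2), 50, 8,
              dimnames = list(paste0("P", 1:50), paste0("r", 1:8)))
  groups <- rep(c("A", "B"), each = 4)
  m[1, 1:4] <- NA   # MNAR in A
  m[2, 5] <- NA     # MAR
  lab <- classify_missingness(m, groups)
  out <- impute_mixed(m, lab, groups, strategy_mar = "knn",
                      strategy_mnar = "zero_floor")
  expect_false(anyNA(out))
  expect_equal(out[1, 1:4], setNames(rep(min(m, na.rm = TRUE), 4),
                                     paste0("r", 1:4)))
  obs <- !is.na(m)
  expect_identical(out[obs], m[obs])
  # complete matrix -> identity for any strategy
  mc <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("P", 1:5), paste0("r", 1:4)))
  labc <- classify_missingness(mc, rep("A", 4))
  expect_identical(impute_mixed(mc, labc, rep("A", 4)), mc)
})

test_that("minprob draws match the specified low-abundance distribution", {
  set.seed(5)
  n <- 10000
  m <- matrix(rnorm(n * 2 + 2000, 20, 2), n + 1000, 2)
  m <- cbind(m, rnorm(nrow(m), 20, 2))
  colnames(m) <- paste0("r", 1:3); rownames(m) <- paste0("P", 1:nrow(m))
  groups <- c("A", "A", "B")
  miss <- seq_len(n)
  m[cbind(miss, 1L)] <- NA  # MAR cells in run 1 (others observed)
  lab <- classify_missingness(m, groups)
  out <- impute_mixed(m, lab, groups, strategy_mar = "minprob", seed = 99)
  drawn <- out[miss, 1]
  q01 <- quantile(m[-miss, 1], 0.01, names = FALSE, na.rm = TRUE)
  sd0 <- median(apply(m, 2, sd, na.rm = TRUE))
  expect_lt(abs(mean(drawn) - q01), 0.1)
  expect_lt(abs(sd(drawn) - sd0) / sd0, 0.05)
  # reproducible under the seed
  out2 <- impute_mixed(m, lab, groups, strategy_mar = "minprob", seed = 99)
  expect_identical(out, out2)
})

test_that("moderated t reduces to the classical pooled t when d0 = 0", {
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1), 1)
    r <- moderated_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$t_mod, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    expect_equal(r$df_total, unname(ref$parameter))
  }
  # equal group means: log_fc 0, p = 1
  r0 <- moderated_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r0$log_fc, 0)
  expect_equal(r0$p, 1)
})

test_that("empirical-Bayes moments agree with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(11)
  for (df in c(4, 10)) {
    s2 <- rchisq(400, df) / df * exp(rnorm(400, 0, 0.6))
    eb <- eb_moments(s2, df)
    sq <- limma::squeezeVar(s2, df = df)
    expect_equal(eb$d0, sq$df.prior, tolerance = 1e-6)
    expect_equal(eb$s02, sq$var.prior, tolerance = 1e-6)
  }
})

test_that("BH and Hommel match brute-force references on small vectors", {
  set.seed(13)
  for (i in 1:40) {
    p <- runif(sample(1:8, 1))
    expect_equal(adjust_bh(p), brute_bh(p), tolerance = 1e-12)
    expect_equal(adjust_hommel(p), brute_hommel(p), tolerance = 1e-12)
  }
  # hand step-up example and the single-p identity
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_hommel(0.3), 0.3)
  # Hommel never exceeds Bonferroni
  for (i in 1:100) {
    p <- runif(sample(2:20, 1))
    expect_true(all(adjust_hommel(p) <= pmin(1, length(p) * p) + 1e-12))
  }
})

test_that("Type-II ANOVA matches car on unbalanced data and Type-I when balanced", {
  skip_if_not_installed("car")
  set.seed(17)
  d <- expand.grid(A = c("a", "b"), B = c("x", "y", "z"), rep = 1:3)[, 1:2]
  d <- d[-c(2, 7), ]
  y <- rnorm(nrow(d)) + 2 * (d$A == "b")
  fa <- factorial_anova(y, d, c("A", "B"))
  ref <- car::Anova(stats::lm(y ~ A * B, data = d), type = 2)
  expect_equal(fa$sum_sq, ref$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(fa$p, ref$`Pr(>F)`[1:3], tolerance = 1e-10)

  # balanced design: Type-II equals sequential SS
  db <- expand.grid(A = c("a", "b"), B = c("x", "y"), rep = 1:4)[, 1:2]
  yb <- rnorm(nrow(db)) + (db$A == "b") + 0.5 * (db$B == "y")
  fb <- factorial_anova(yb, db, c("A", "B"))
  seq_ss <- stats::anova(stats::lm(yb ~ A * B, data = db))
  expect_equal(fb$sum_sq, seq_ss$`Sum Sq`[1:3], tolerance = 1e-10)

  # one-factor design equals the classical one-way F
  d1 <- data.frame(g = rep(c("a", "b", "c"), each = 5))
  y1 <- rnorm(15) + (d1$g == "c")
  f1 <- factorial_anova(y1, d1, "g")
  ref1 <- stats::anova(stats::lm(y1 ~ g, d1))
  expect_equal(f1$F, ref1$`F value`[1], tolerance = 1e-10)
})

test_that("ANOVA recovers a single planted factor and flags degenerate fits", {
  set.seed(19)
  hits_a <- hits_b <- 0
  for (s in 1:20) {
    d <- expand.grid(A = c("a", "b"), B = c("x", "y"), rep = 1:4)[, 1:2]
    y <- rnorm(nrow(d), 0, 0.5) + 2 * (d$A == "b")  # only A matters
    fa <- factorial_anova(y, d, c("A", "B"))
    if (fa$p[fa$term == "A"] < 0.01) hits_a <- hits_a + 1
    if (fa$p[fa$term == "B"] < 0.01) hits_b <- hits_b + 1
  }
  expect_gte(hits_a, 19)
  expect_lte(hits_b, 3)
  # zero-noise cell means: residual SS 0 -> degenerate, F undefined
  d <- expand.grid(A = c("a", "b"), B = c("x", "y"), rep = 1:2)[, 1:2]
  y <- 1 * (d$A == "b") + 2 * (d$B == "y")
  fd <- factorial_anova(y, d, c("A", "B"))
  expect_true(attr(fd, "degenerate"))
  expect_true(all(is.na(fd$F)))
})

test_that("Tukey HSD matches the reference and covers the true difference", {
  set.seed(23)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 6))
  y <- rnorm(18, 0, 1) + 5 * (d$g == "c")  # one level shifted 5 sigma
  tk <- tukey_hsd(factorial_anova(y, d, "g"), "g")
  ref <- TukeyHSD(stats::aov(y ~ g, d))$g
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(tk$p, unname(ref[, "p adj"]), tolerance = 1e-10)
  ac <- tk[tk$level_a == "c" | tk$level_b == "c", ]
  expect_true(all(ac$p < 0.01))
  # two identical levels: difference exactly 0, p near 1
  base <- rnorm(6)
  y2 <- c(base, base, rnorm(6, 3))
  tk2 <- tukey_hsd(factorial_anova(y2, d, "g"), "g")
  ab <- tk2[tk2$level_a == "b" & tk2$level_b == "a", ]
  expect_equal(ab$diff, 0)
  expect_gt(ab$p, 0.99)

  # CI coverage of the true difference at 95% nominal over 200 simulations
  cover <- 0
  for (s in 1:200) {
    yy <- rnorm(18) + 1.5 * (d$g == "c")
    tt <- tukey_hsd(factorial_anova(yy, d, "g"), "g")
    row <- tt[tt$level_a == "c" & tt$level_b == "a", ]
    if (row$lwr <= 1.5 && 1.5 <= row$upr) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.90)
})
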