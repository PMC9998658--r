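#' @title Statistical kernels
#' @description Self-contained implementations of the statistics the
#'   pipeline relies on: missing-value classification (MNAR vs MAR), the
#'   imputation strategies, the empirical-Bayes moderated two-group test,
#'   Benjamini-Hochberg and Hommel multiple-testing adjustment, Type-II
#'   factorial ANOVA and Tukey's HSD. Formulas are documented on each
#'   function; unit tests cross-check them against independent references.
#' @name stats_core
NULL

#' Classify missing observations as MNAR or MAR per (protein, group)
#'
#' A protein is labelled MNAR (missing not at random, i.e. below the
#' detection limit) in a group iff it is missing in all runs of that group
#' while observed in at least one run of some other group. Any other missing
#' cells are MAR. A (protein, group) with no missing cells is `complete`.
#'
#' @param m numeric matrix (proteins x runs) with `NA` for missing.
#' @param groups character/factor vector of group labels, one per column.
#' @return character matrix proteins x groups with entries
#'   `"complete"`, `"MAR"` or `"MNAR"`.
#' @export
classify_missingness <- function(m, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  obs <- !is.na(m)
  n_obs <- sapply(gl, function(g) rowSums(obs[, groups == g, drop = FALSE]))
  n_run <- vapply(gl, function(g) sum(groups == g), integer(1))
  n_obs <- matrix(n_obs, nrow = nrow(m), dimnames = list(rownames(m), gl))
  total_obs <- rowSums(n_obs)
  lab <- matrix("MAR", nrow(m), length(gl), dimnames = list(rownames(m), gl))
  for (j in seq_along(gl)) {
    complete <- n_obs[, j] == n_run[j]
    mnar <- n_obs[, j] == 0 & (total_obs - n_obs[, j]) > 0
    lab[complete, j] <- "complete"
    lab[mnar, j] <- "MNAR"
  }
  lab
}

#' Impute missing values with a mixed MNAR/MAR strategy
#'
#' Cells whose (protein, group) is labelled MNAR receive the MNAR strategy;
#' all remaining missing cells receive the MAR strategy. Observed cells are
#' never touched.
#'
#' MAR strategies: `knn` (k-nearest proteins by Euclidean distance on shared
#' observed runs, inverse-distance-weighted mean; falls back to the run
#' median with a warning when fewer than `k` usable neighbours exist) or
#' `minprob` (draws from Normal(q0.01 of the run's observed values, median
#' per-run SD), a low-abundance random draw).
#'
#' MNAR strategies: `zero_floor` (the dataset's global minimum observed
#' value — a detection-limit floor; set `floor_value = 0` for a literal
#' zero) or `ppca` (rank-2 probabilistic PCA reconstruction fitted by EM).
#'
#' @param m numeric matrix (proteins x runs), typically log2 scale.
#' @param labels missingness labels from [classify_missingness()].
#' @param groups group label per column (same as used for `labels`).
#' @param strategy_mar `"knn"` or `"minprob"`.
#' @param strategy_mnar `"zero_floor"` or `"ppca"`.
#' @param k neighbours for kNN.
#' @param floor_value optional explicit floor for `zero_floor` (default:
#'   global observed minimum).
#' @param seed integer seed for the stochastic `minprob` draws.
#' @return the completed matrix (no `NA` left).
#' @export
impute_mixed <- function(m, labels, groups,
                         strategy_mar = c("knn", "minprob"),
                         strategy_mnar = c("zero_floor", "ppca"),
                         k = 10, floor_value = NULL, seed = 1L) {
  strategy_mar <- match.arg(strategy_mar)
  strategy_mnar <- match.arg(strategy_mnar)
  if (!anyNA(m)) return(m)
  groups <- as.character(groups)
  gl <- colnames(labels)
  mnar_cell <- matrix(FALSE, nrow(m), ncol(m))
  for (g in gl) {
    cols <- which(groups == g)
    mnar_cell[, cols] <- labels[, g] == "MNAR"
  }
  mnar_cell <- mnar_cell & is.na(m)
  mar_cell <- is.na(m) & !mnar_cell

  out <- m
  if (any(mnar_cell)) {
    if (strategy_mnar == "zero_floor") {
      fl <- if (is.null(floor_value)) min(m, na.rm = TRUE) else floor_value
      out[mnar_cell] <- fl
    } else {
      rec <- ppca_reconstruct(m, n_comp = 2, tol = 1e-6, max_iter = 500, seed = seed)
      out[mnar_cell] <- rec[mnar_cell]
    }
  }
  if (any(mar_cell)) {
    if (strategy_mar == "knn") {
      out <- impute_knn_cells(m, out, mar_cell, k = k)
    } else {
      out <- impute_minprob_cells(m, out, mar_cell, seed = seed)
    }
  }
  stopifnot(!anyNA(out))
  out
}

impute_knn_cells <- function(m, out, cells, k = 10) {
  fell_back <- 0L
  run_median <- apply(m, 2, stats::median, na.rm = TRUE)
  obs <- !is.na(m)
  prot_idx <- which(rowSums(cells) > 0)
  for (i in prot_idx) {
    cand <- which(seq_len(nrow(m)) != i)
    shared <- obs[cand, , drop = FALSE] & rep(obs[i, ], each = length(cand))
    nsh <- rowSums(shared)
    d2 <- rowSums(((m[cand, , drop = FALSE] -
                    rep(m[i, ], each = length(cand)))^2) * shared, na.rm = TRUE)
    d <- sqrt(d2 / pmax(nsh, 1))
    d[nsh < 2] <- Inf
    for (j in which(cells[i, ])) {
      usable <- which(is.finite(d) & obs[cand, j])
      if (length(usable) < k) {
        out[i, j] <- run_median[j]
        fell_back <- fell_back + 1L
        next
      }
      nb <- usable[order(d[usable])][seq_len(k)]
      w <- 1 / (d[nb] + 1e-9)
      out[i, j] <- sum(w * m[cand[nb], j]) / sum(w)
    }
  }
  if (fell_back)
    warning(fell_back, " cell(s) had fewer than k usable kNN neighbours; ",
            "imputed with the run median")
  out
}

impute_minprob_cells <- function(m, out, cells, seed = 1L) {
  run_sd <- apply(m, 2, stats::sd, na.rm = TRUE)
  sd0 <- stats::median(run_sd, na.rm = TRUE)
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- 1e-3
  q_lo <- apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(min(m, na.rm = TRUE))
    stats::quantile(v, 0.01, names = FALSE)
  })
  withr_seed(seed, {
    for (j in which(colSums(cells) > 0)) {
      idx <- which(cells[, j])
      out[idx, j] <- stats::rnorm(length(idx), mean = q_lo[j], sd = sd0)
    }
  })
  out
}

# run expr under a local RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Rank-restricted probabilistic PCA reconstruction of an incomplete matrix
#'
#' EM-style alternation: missing cells start at row means, the matrix is
#' reconstructed from its leading principal components, and missing cells
#' are refilled from the reconstruction until the update changes by less
#' than `tol` (relative Frobenius norm) or `max_iter` is hit.
#'
#' @param m matrix with `NA`s.
#' @param n_comp number of components (default 2).
#' @param tol,max_iter convergence controls.
#' @param seed seed (used only to break ties in degenerate SVDs).
#' @return the reconstructed (complete) matrix, observed cells restored.
#' @export
ppca_reconstruct <- function(m, n_comp = 2, tol = 1e-6, max_iter = 500, seed = 1L) {
  miss <- is.na(m)
  if (!any(miss)) return(m)
  rmean <- rowMeans(m, na.rm = TRUE)
  rmean[!is.finite(rmean)] <- mean(m, na.rm = TRUE)
  x <- m
  x[miss] <- rmean[row(m)[miss]]
  n_comp <- min(n_comp, dim(m) - 1L)
  for (it in seq_len(max_iter)) {
    mu <- rowMeans(x)
    xc <- x - mu
    sv <- svd(xc, nu = n_comp, nv = n_comp)
    d <- sv$d[seq_len(n_comp)]
    rec <- sv$u %*% (d * t(sv$v)) + mu
    delta <- sqrt(sum((rec[miss] - x[miss])^2)) /
      max(sqrt(sum(x[miss]^2)), 1e-12)
    x[miss] <- rec[miss]
    if (delta < tol) break
  }
  x
}

## ---- moderated two-group test ------------------------------------------

#' Empirical-Bayes hyperparameters by method of moments on log variances
#'
#' Given per-protein sample variances `s2` with residual degrees of freedom
#' `df`, models s2 as scaled F around a prior variance s0^2 with prior df
#' d0, and estimates (d0, s0^2) by matching the first two moments of
#' log(s2): with e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2),
#' E\[e\] = log(s0^2) + digamma(d0/2) - log(d0/2) and
#' Var\[e\] = trigamma(df/2) + trigamma(d0/2). A non-positive excess
#' variance gives d0 = Inf (fully shared variance).
#'
#' @param s2 numeric vector of sample variances (>0 entries used).
#' @param df residual df per variance (scalar or vector).
#' @return list with `d0` and `s02`.
#' @export
eb_moments <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[keep]; df <- df[keep]
  n <- length(s2)
  if (n < 2) return(list(d0 = 0, s02 = if (n) s2 else 1))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2) * n / (n - 1) - mean(trigamma(df / 2))
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s02 = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve trigamma(y) = x, x > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated two-group t-test for one protein
#'
#' The pooled sample variance is shrunk toward the prior:
#' s2_post = (d0 * s0^2 + df * s2) / (d0 + df), and
#' t_mod = log_fc / (s_post * sqrt(1/nA + 1/nB)) is referred to a
#' t-distribution with df_total = df + d0. With d0 = 0 this is exactly the
#' classical pooled two-sample t-test.
#'
#' @param a,b numeric vectors of (log2) values for the two groups, each of
#'   length >= 2 after removing `NA`.
#' @param d0,s02 empirical-Bayes prior df and prior variance (see
#'   [eb_moments()]); defaults give the unmoderated test.
#' @return list with `log_fc`, `s2_pooled`, `s2_prior`, `df_prior`,
#'   `t_mod`, `df_total`, `p`.
#' @export
moderated_t <- function(a, b, d0 = 0, s02 = 0) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need >= 2 observations per group")
  df <- na + nb - 2
  log_fc <- mean(a) - mean(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (is.infinite(d0)) {
    s2_post <- s02; df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- if (se > 0) log_fc / se else sign(log_fc) * Inf
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(log_fc = log_fc, s2_pooled = s2, s2_prior = s02, df_prior = d0,
       t_mod = t_mod, df_total = df_total, p = p)
}

#' Moderated two-group test across a matrix of proteins
#'
#' Estimates the empirical-Bayes prior from all proteins' pooled variances,
#' then applies the moderated t row-wise.
#'
#' @param A,B matrices (proteins x runs) for the two groups, complete
#'   (imputed) values.
#' @param moderate if `FALSE`, d0 is forced to 0 (classical t).
#' @return data.frame with one row per protein: `log_fc`, `s2_pooled`,
#'   `t_mod`, `df_total`, `p`, plus attributes `d0`, `s02`.
#' @export
moderated_t_matrix <- function(A, B, moderate = TRUE) {
  stopifnot(nrow(A) == nrow(B))
  na <- ncol(A); nb <- ncol(B)
  if (na < 2 || nb < 2) stop("need >= 2 runs per group")
  df <- na + nb - 2
  ma <- rowMeans(A); mb <- rowMeans(B)
  s2 <- (rowSums((A - ma)^2) + rowSums((B - mb)^2)) / df
  if (moderate) {
    prior <- eb_moments(s2, df)
  } else {
    prior <- list(d0 = 0, s02 = 0)
  }
  d0 <- prior$d0; s02 <- prior$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2)); df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  log_fc <- ma - mb
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log_fc / se, sign(log_fc) * Inf)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(protein_id = rownames(A) %||% as.character(seq_along(p)),
                    log_fc = log_fc, s2_pooled = s2, t_mod = t_mod,
                    df_total = rep_len(df_total, length(p)), p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- multiple testing ---------------------------------------------------

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: with order statistics p_(1) <= ... <= p_(n), the
#' adjusted value is min over j >= i of n * p_(j) / j, capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
adjust_bh <- function(p) {
  n <- length(p)
  if (n <= 1) return(pmin(1, p))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Hommel FWER adjustment
#'
#' Closed-testing procedure based on Simes tests, computed with the
#' quadratic-time recursion over hypothesis subsets of decreasing size
#' (the standard closed algorithm). For a single p-value it is the identity.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
adjust_hommel <- function(p) {
  n <- length(p)
  if (n <= 1) return(pmin(1, p))
  o <- order(p)
  ps <- p[o]
  q <- pa <- rep(min(n * ps / seq_len(n)), n)
  if (n > 2) for (m in (n - 1):2) {
    i1 <- seq_len(n - m + 1L)
    i2 <- (n - m + 2L):n
    q1 <- min(m * ps[i2] / (2:m))
    q[i1] <- pmin(m * ps[i1], q1)
    q[i2] <- q[n - m + 1L]
    pa <- pmax(pa, q)
  }
  pmin(1, pmax(pa, ps))[order(o)]
}

## ---- factorial ANOVA ----------------------------------------------------

#' Factorial ANOVA with Type-II sums of squares
#'
#' Fits a fully crossed linear model in the supplied factors and computes,
#' for every term, the Type-II sum of squares: the increase in residual SS
#' from dropping that term from the sub-model containing every term that
#' does not contain it (respecting marginality). Type-II is used because
#' post-filter designs are typically unbalanced; on a perfectly balanced
#' design it coincides with sequential (Type-I) SS. Interaction terms that
#' are aliased (no estimable columns) are dropped and noted.
#'
#' @param values numeric response vector.
#' @param design data.frame of factors (one column per factor).
#' @param factors character vector naming the columns of `design` to use.
#' @param interactions include interaction terms (default TRUE).
#' @return an object of class `anova_result`: data.frame (`term`, `sum_sq`,
#'   `df`, `F`, `p`) with attributes `df_resid`, `sigma2`, `degenerate`,
#'   `dropped_terms`, and the model frame for post-hoc tests.
#' @export
factorial_anova <- function(values, design, factors = names(design),
                            interactions = TRUE) {
  stopifnot(length(values) == nrow(design))
  dat <- design[, factors, drop = FALSE]
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  # single-level factors carry no information; drop them
  keep <- vapply(dat, function(x) nlevels(x) > 1, logical(1))
  dropped_factors <- factors[!keep]
  factors <- factors[keep]
  if (!length(factors)) stop("no factor with >= 2 levels")
  dat <- dat[, factors, drop = FALSE]
  dat$.y <- values

  rhs <- if (interactions && length(factors) > 1)
    paste0("(", paste(factors, collapse = " * "), ")")
  else paste(factors, collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))

  mm <- stats::model.matrix(form, dat)
  asg <- attr(mm, "assign")
  labs <- attr(stats::terms(form), "term.labels")

  rss_of <- function(cols) {
    if (!length(cols)) cols <- 1L  # intercept only
    fit <- stats::lm.fit(mm[, cols, drop = FALSE], values)
    list(rss = sum(fit$residuals^2), rank = fit$rank)
  }

  full_cols <- seq_len(ncol(mm))
  full <- rss_of(full_cols)
  df_resid <- length(values) - full$rank
  if (df_resid < 1) stop("no residual degrees of freedom")
  sigma2 <- full$rss / df_resid
  degenerate <- full$rss < 1e-10 * max(sum(values^2), 1)

  contains <- function(a, b) {
    # does term label a contain term label b (marginality)?
    fa <- strsplit(a, ":", fixed = TRUE)[[1]]
    fb <- strsplit(b, ":", fixed = TRUE)[[1]]
    all(fb %in% fa)
  }

  rows <- list(); dropped_terms <- character()
  for (ti in seq_along(labs)) {
    lab <- labs[ti]
    others <- which(vapply(labs, function(l) !contains(l, lab), logical(1)))
    base_cols <- c(1L, which(asg %in% others))
    with_cols <- c(base_cols, which(asg == ti))
    f0 <- rss_of(base_cols); f1 <- rss_of(with_cols)
    df_t <- f1$rank - f0$rank
    if (df_t < 1) { dropped_terms <- c(dropped_terms, lab); next }
    ss <- f0$rss - f1$rss
    Fv <- if (degenerate) NA_real_ else (ss / df_t) / sigma2
    pv <- if (is.na(Fv)) NA_real_ else stats::pf(Fv, df_t, df_resid, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(term = lab, sum_sq = ss, df = df_t,
                                            F = Fv, p = pv, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, class = c("anova_result", "data.frame"),
            df_resid = df_resid, sigma2 = sigma2, degenerate = degenerate,
            dropped_terms = c(dropped_factors, dropped_terms),
            model_data = dat, factors = factors)
}

#' Tukey's Honest Significant Difference post-hoc test
#'
#' All pairwise level differences of one factor, with Tukey-Kramer standard
#' errors se = sqrt(MSE/2 * (1/n_i + 1/n_j)) and p-values from the
#' studentized range distribution with the ANOVA's residual df. The returned
#' `p_adj` column additionally applies BH across the table's comparisons.
#'
#' @param anova an `anova_result` from [factorial_anova()].
#' @param factor_name which factor's levels to compare.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return data.frame: `level_a`, `level_b`, `diff`, `lwr`, `upr`, `p`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(anova, factor_name, conf_level = 0.95) {
  dat <- attr(anova, "model_data")
  if (!factor_name %in% attr(anova, "factors"))
    stop("unknown factor: ", factor_name)
  f <- dat[[factor_name]]
  y <- dat$.y
  mse <- attr(anova, "sigma2")
  dfr <- attr(anova, "df_resid")
  lev <- levels(f)
  k <- length(lev)
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  cmb <- utils::combn(k, 2)
  qcrit <- stats::qtukey(conf_level, k, dfr)
  rows <- apply(cmb, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[j] - means[i]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    stat <- if (se > 0) abs(d) / se else Inf
    p <- stats::ptukey(stat, k, dfr, lower.tail = FALSE)
    c(d, d - qcrit * se, d + qcrit * se, p)
  })
  out <- data.frame(level_a = lev[cmb[2, ]], level_b = lev[cmb[1, ]],
                    diff = rows[1, ], lwr = rows[2, ], upr = rows[3, ],
                    p = rows[4, ], stringsAsFactors = FALSE)
  out$p_adj <- adjust_bh(out$p)
  rownames(out) <- NULL
  out
}
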