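#' @title Biased targeted random walks on an effector network
#' @description Attribution of functional outputs to individual effector
#'   pathways: a confidence-filtered PPI subnetwork is rooted at the bait
#'   (source), which connects by directed edges to its effectors only;
#'   memoryless targeted walks start at the source and step to a uniformly
#'   chosen neighbour, up-weighted by `bias_factor` (default 20) when the
#'   neighbour is in the condition's measured interactome
#'   (P(in AP-MS) = 20 * P(not in AP-MS)); a walk succeeds when it reaches
#'   its target within walklen = shortest path + 2 steps. Retained
#'   high-frequency paths are decomposed into condition-specific
#'   information-flow networks and effector traversal weights. An exact
#'   depth-limited enumeration serves as the oracle for the stochastic
#'   engine.
#' @name random_walk
NULL

#' Build the effector network from a scored edge list
#'
#' Edges below `min_score` are removed first (strictly: a score equal to
#' the threshold is kept); then every node farther than `max_sp` hops from
#' the nearest effector (over surviving edges) is removed with its incident
#' edges. The source is attached afterwards by directed edges to the
#' effectors only; no undirected edge touches the source.
#'
#' @param edges data.frame (`node_a`, `node_b`, `score`) of undirected
#'   edges, scores in \[0, 1\].
#' @param effectors character vector of effector node ids (must be in the
#'   edge list's node universe).
#' @param source source (bait) node id; must not appear in `edges`.
#' @param min_score confidence threshold (default 0.7).
#' @param max_sp maximum hops to the nearest effector (default 4).
#' @return an `effector_network`: list with `nodes`, `adj` (named list of
#'   undirected neighbours, source excluded), `edges`, `source`,
#'   `effectors`.
#' @export
build_network <- function(edges, effectors, source, min_score = 0.7,
                          max_sp = 4) {
  universe <- unique(c(edges$node_a, edges$node_b))
  missing_eff <- setdiff(effectors, universe)
  if (length(missing_eff))
    stop("effector(s) not in the edge-list node universe: ",
         paste(missing_eff, collapse = ", "))
  if (source %in% universe) {
    # only directed source->effector edges are allowed; drop the rest
    keep <- edges$node_a != source & edges$node_b != source
    edges <- edges[keep, , drop = FALSE]
  }
  edges <- edges[edges$score >= min_score, , drop = FALSE]

  nodes <- unique(c(edges$node_a, edges$node_b, effectors))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[c("node_a", "node_b")],
                                       vertices = nodes, directed = FALSE)
    d <- igraph::distances(g, v = effectors, to = nodes)
    mind <- apply(d, 2, min)
    keep_nodes <- nodes[mind <= max_sp]
  } else {
    keep_nodes <- character()
  }
  iso <- setdiff(effectors, unique(c(edges$node_a, edges$node_b)))
  if (length(iso))
    warning("effector(s) isolated after score filtering: ",
            paste(iso, collapse = ", "))
  keep_nodes <- union(keep_nodes, effectors)
  edges <- edges[edges$node_a %in% keep_nodes &
                 edges$node_b %in% keep_nodes, , drop = FALSE]
  adj <- stats::setNames(vector("list", length(keep_nodes)), keep_nodes)
  for (nm in keep_nodes) adj[[nm]] <- character()
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(nodes = sort(keep_nodes), adj = adj,
                 edges = edges[order(edges$node_a, edges$node_b), ,
                               drop = FALSE],
                 source = source, effectors = sort(effectors)),
            class = "effector_network")
}

#' @export
print.effector_network <- function(x, ...) {
  cat(sprintf("effector_network: %d nodes, %d undirected edges, source %s -> %d effectors\n",
              length(x$nodes), nrow(x$edges), x$source, length(x$effectors)))
  invisible(x)
}

# neighbours of a node, honouring the directed source edges
network_neighbours <- function(network, node) {
  if (node == network$source) network$effectors else network$adj[[node]]
}

#' Biased step distribution at a node
#'
#' Each neighbour gets weight `bias_factor` if it is in the condition's
#' evidence set (the AP-MS interactome) and 1 otherwise; weights are
#' normalized to probabilities, so P(in AP-MS) = bias_factor * P(not in
#' AP-MS) for any pair of one in-evidence and one out-of-evidence
#' neighbour. The actual probabilities depend on the number of connecting
#' nodes.
#'
#' @param network an `effector_network`.
#' @param current current node (may be the source).
#' @param evidence character vector of in-interactome node ids.
#' @param bias_factor up-weighting factor (default 20, >= 1).
#' @return named probability vector over the neighbours.
#' @export
step_distribution <- function(network, current, evidence, bias_factor = 20) {
  stopifnot(bias_factor >= 1)
  nb <- network_neighbours(network, current)
  if (!length(nb)) stop("node ", current, " has no neighbour")
  w <- ifelse(nb %in% evidence, bias_factor, 1)
  stats::setNames(w / sum(w), nb)
}

#' Walk length for a target: shortest path + 2
#'
#' The shortest path is computed on the constructed network with the
#' directed source edges respected (the source reaches the rest of the
#' graph only through its effectors).
#'
#' @param network an `effector_network`.
#' @param target target node id.
#' @return integer walk length.
#' @export
walk_length <- function(network, target) {
  if (!target %in% network$nodes) stop("target not in network: ", target)
  if (target %in% network$effectors) return(1L + 2L)
  if (!nrow(network$edges)) stop("target unreachable: ", target)
  g <- igraph::graph_from_data_frame(network$edges[c("node_a", "node_b")],
                                     vertices = network$nodes,
                                     directed = FALSE)
  d <- igraph::distances(g, v = network$effectors, to = target)
  sp <- 1 + min(d)
  if (!is.finite(sp)) stop("target unreachable: ", target)
  as.integer(sp) + 2L
}

#' Walk specification
#'
#' @param target target node.
#' @param n_walks number of walks.
#' @param evidence in-interactome node set for the condition.
#' @param bias_factor bias (default 20).
#' @param walklen maximum steps; `NULL` computes shortest path + 2 via
#'   [walk_length()] when the network is supplied to [run_walks()].
#' @param seed integer seed.
#' @return a `walk_spec` list.
#' @export
walk_spec <- function(target, n_walks, evidence = character(),
                      bias_factor = 20, walklen = NULL, seed = 1L) {
  stopifnot(n_walks >= 1, bias_factor >= 1)
  structure(list(target = target, n_walks = as.integer(n_walks),
                 evidence = evidence, bias_factor = bias_factor,
                 walklen = walklen, seed = as.integer(seed)),
            class = "walk_spec")
}

# per-node transition tables under a given evidence set: list of
# list(nb = integer neighbour indices, cp = cumulative probabilities)
transition_tables <- function(network, evidence, bias_factor) {
  all_nodes <- c(network$source, network$nodes)
  idx <- stats::setNames(seq_along(all_nodes), all_nodes)
  tabs <- vector("list", length(all_nodes))
  for (i in seq_along(all_nodes)) {
    nb <- network_neighbours(network, all_nodes[i])
    if (!length(nb)) { tabs[[i]] <- NULL; next }
    w <- ifelse(nb %in% evidence, bias_factor, 1)
    tabs[[i]] <- list(nb = unname(idx[nb]), cp = cumsum(w) / sum(w))
  }
  list(tabs = tabs, idx = idx, names = all_nodes)
}

#' Run biased targeted random walks
#'
#' Each walk starts at the source and samples steps from
#' [step_distribution()]; it succeeds as soon as the target is reached and
#' fails after `walklen` steps without absorption. Walks may revisit nodes
#' (the bias rule is memoryless). Fully reproducible under the spec's seed.
#'
#' @param network an `effector_network`.
#' @param spec a [walk_spec()]; the target must differ from the source and
#'   be reachable.
#' @return a `path_ensemble`: list with `paths` (data.frame `path`,
#'   `count`, `freq`; paths as `"A->B->C"` node sequences from source to
#'   target), `n_walks`, `n_success`, `target`, `walklen`.
#' @export
run_walks <- function(network, spec) {
  if (spec$target == network$source) stop("target equals source")
  walklen <- spec$walklen %||% walk_length(network, spec$target)
  tt <- transition_tables(network, spec$evidence, spec$bias_factor)
  tgt <- tt$idx[[spec$target]]
  src <- tt$idx[[network$source]]
  n <- spec$n_walks

  steps <- matrix(0L, n, walklen + 1L)
  steps[, 1L] <- src
  cur <- rep.int(src, n)
  active <- rep.int(TRUE, n)
  done_at <- integer(n)
  withr_seed(spec$seed, {
    for (s in seq_len(walklen)) {
      ai <- which(active)
      if (!length(ai)) break
      snap <- cur[ai]  # freeze positions: cur mutates inside the loop
      for (v in unique(snap)) {
        tb <- tt$tabs[[v]]
        wi <- ai[snap == v]
        if (is.null(tb)) { active[wi] <- FALSE; next }  # dead end: fail
        u <- stats::runif(length(wi))
        nxt <- tb$nb[findInterval(u, tb$cp) + 1L]
        steps[wi, s + 1L] <- nxt
        cur[wi] <- nxt
      }
      hit <- active & cur == tgt
      done_at[hit] <- s
      active[hit] <- FALSE
    }
  })
  ok <- done_at > 0L
  n_success <- sum(ok)
  if (n_success) {
    sm <- steps[ok, , drop = FALSE]
    # blank out columns after absorption so equal paths key identically
    col <- col(sm)
    sm[col > done_at[ok] + 1L] <- 0L
    key <- do.call(paste, c(as.data.frame(sm), sep = ","))
    cnt <- table(key)
    seqs <- lapply(strsplit(names(cnt), ",", fixed = TRUE), function(v) {
      v <- as.integer(v); tt$names[v[v > 0L]]
    })
    paths <- data.frame(path = vapply(seqs, paste, "", collapse = "->"),
                        count = as.integer(cnt), stringsAsFactors = FALSE)
    paths$freq <- paths$count / n
    paths <- paths[order(-paths$count, nchar(paths$path), paths$path), ,
                   drop = FALSE]
    rownames(paths) <- NULL
  } else {
    paths <- data.frame(path = character(), count = integer(),
                        freq = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(paths = paths, n_walks = n, n_success = n_success,
                 target = spec$target, walklen = walklen),
            class = "path_ensemble")
}

#' Exact enumeration of targeted-walk path probabilities
#'
#' Depth-limited expansion of every node sequence from the source with
#' per-step probabilities from [step_distribution()], absorbing at the
#' target. The probabilities of the successful sequences plus the failure
#' probability sum to 1. Feasible for small graphs only; expansion is
#' guarded at `max_states` partial states.
#'
#' @param network an `effector_network`.
#' @param spec a [walk_spec()] (its `n_walks` and `seed` are ignored).
#' @param max_states guard on the number of expanded partial states.
#' @return list: `paths` (data.frame `path`, `prob`), `p_success`,
#'   `p_fail`, `walklen`.
#' @export
enumerate_paths_exact <- function(network, spec, max_states = 1e6) {
  if (spec$target == network$source) stop("target equals source")
  walklen <- spec$walklen %||% walk_length(network, spec$target)
  paths <- new.env(parent = emptyenv())
  states <- 0L
  p_fail <- 0
  recurse <- function(node, prob, trail, depth) {
    states <<- states + 1L
    if (states > max_states) stop("state guard exceeded (", max_states, ")")
    if (node == spec$target) {
      key <- paste(trail, collapse = "->")
      paths[[key]] <- (if (is.null(paths[[key]])) 0 else paths[[key]]) + prob
      return(invisible())
    }
    if (depth == walklen) { p_fail <<- p_fail + prob; return(invisible()) }
    nb <- network_neighbours(network, node)
    if (!length(nb)) { p_fail <<- p_fail + prob; return(invisible()) }
    pr <- step_distribution(network, node, spec$evidence, spec$bias_factor)
    for (i in seq_along(nb)) {
      recurse(nb[i], prob * pr[[i]], c(trail, nb[i]), depth + 1L)
    }
  }
  recurse(network$source, 1, network$source, 0L)
  keys <- ls(paths)
  out <- data.frame(path = keys,
                    prob = vapply(keys, function(k) paths[[k]], numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prob, nchar(out$path), out$path), , drop = FALSE]
  rownames(out) <- NULL
  list(paths = out, p_success = sum(out$prob), p_fail = p_fail,
       walklen = walklen)
}

#' Filter and rank walk paths
#'
#' Drops paths observed at a frequency below `min_freq` (the scale-free
#' form of the 100-per-1e8-walks cut) and keeps the top `k` by frequency,
#' with ties broken by shorter path first, then lexicographically, for
#' determinism.
#'
#' @param pe a `path_ensemble` from [run_walks()].
#' @param min_freq minimum count/n_walks (default 1e-6).
#' @param k number of paths kept per target (default 10).
#' @return data.frame `path`, `count`, `freq`, ranked.
#' @export
filter_and_rank_paths <- function(pe, min_freq = 1e-6, k = 10) {
  p <- pe$paths
  p <- p[p$freq >= min_freq, , drop = FALSE]
  nseg <- lengths(strsplit(p$path, "->", fixed = TRUE))
  p <- p[order(-p$freq, nseg, p$path), , drop = FALSE]
  p <- utils::head(p, k)
  rownames(p) <- NULL
  p
}

#' Condition-specific information-flow network from retained paths
#'
#' Every retained path contributes its consecutive-node edges weighted by
#' the path's frequency; weights accumulate across paths and targets.
#'
#' @param ranked_paths a data.frame (`path`, `freq`) or a list of them
#'   (one per target).
#' @return data.frame `from`, `to`, `weight`.
#' @export
condition_network <- function(ranked_paths) {
  if (is.data.frame(ranked_paths)) ranked_paths <- list(ranked_paths)
  acc <- new.env(parent = emptyenv())
  for (rp in ranked_paths) {
    for (i in seq_len(nrow(rp))) {
      nodes <- strsplit(rp$path[i], "->", fixed = TRUE)[[1]]
      if (length(nodes) < 2) next
      for (j in seq_len(length(nodes) - 1L)) {
        key <- paste(nodes[j], nodes[j + 1L], sep = "\r")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + rp$freq[i]
      }
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    weight = vapply(keys, function(k) acc[[k]], numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Effector traversal weights from retained paths
#'
#' The traversal weight of an effector is the sum over retained paths
#' containing it of the path's frequency (`mode = "frequency"`, scale-free
#' in the number of walks), or the number of retained paths containing it
#' (`mode = "count"`).
#'
#' @param ranked_paths data.frame (`path`, `freq`) or list of them.
#' @param effectors character vector of effector ids.
#' @param mode `"frequency"` (default) or `"count"`.
#' @return named numeric vector over the effectors.
#' @export
effector_traversal <- function(ranked_paths, effectors,
                               mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  if (is.data.frame(ranked_paths)) ranked_paths <- list(ranked_paths)
  w <- stats::setNames(numeric(length(effectors)), effectors)
  for (rp in ranked_paths) {
    for (i in seq_len(nrow(rp))) {
      nodes <- strsplit(rp$path[i], "->", fixed = TRUE)[[1]]
      hit <- effectors[effectors %in% nodes]
      w[hit] <- w[hit] + if (mode == "frequency") rp$freq[i] else 1
    }
  }
  w
}

#' Effector traversal matrix across conditions
#'
#' @param per_condition named list: condition -> list/data.frame of ranked
#'   paths.
#' @inheritParams effector_traversal
#' @return effectors x conditions matrix of traversal weights.
#' @export
effector_traversal_matrix <- function(per_condition, effectors,
                                      mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  m <- vapply(per_condition, effector_traversal, numeric(length(effectors)),
              effectors = effectors, mode = mode)
  matrix(m, nrow = length(effectors),
         dimnames = list(effectors, names(per_condition)))
}
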