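# Conditional-independence network over score lipids, community detection,
# cluster scores, and direct-effect classification against outcomes.

# combn with the scalar-x gotcha removed (combn(3, 1) would enumerate 1:3)
combn_sets <- function(x, m) {
  if (m == 0L) return(list(x[0]))
  if (length(x) == 1L) return(if (m == 1L) list(x) else list())
  utils::combn(x, m, simplify = FALSE)
}

#' Fisher-z partial correlation test
#'
#' Tests the partial correlation of columns `i` and `j` given the
#' conditioning set `S`, via inversion of the correlation submatrix and the
#' Fisher z-transform with a two-sided normal reference.
#'
#' @param data numeric matrix (n x p), complete, log scale.
#' @param i,j column indices or names.
#' @param conditioning_set integer/character vector of conditioning columns
#'   (may be empty); requires `|S| <= n - 4`.
#' @return p-value, with the sample partial correlation in attribute
#'   `"pcor"`.
#' @export
partial_correlation_test <- function(data, i, j, conditioning_set = integer(0)) {
  stopifnot(is.matrix(data))
  n <- nrow(data)
  S <- conditioning_set
  if (length(S) > n - 4) stop("conditioning set too large: need |S| <= n - 4")
  idx <- c(i, j, S)
  C <- stats::cor(data[, idx, drop = FALSE])
  if (length(S) == 0L) {
    r <- C[1, 2]
  } else {
    P <- tryCatch(solve(C), error = function(e) {
      stop("singular conditioning regression: cannot invert the correlation submatrix")
    })
    r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(n - length(S) - 3) * abs(z)
  p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
  attr(p, "pcor") <- r
  p
}

#' Order-independent (stable) PC skeleton
#'
#' Level-wise conditional-independence edge removal starting from the
#' complete graph. At each level, conditioning sets are drawn from the
#' adjacency sets frozen at the start of the level, which makes the result
#' invariant to variable ordering. Edges removed at some level carry their
#' separating set; surviving edges record the smallest |partial correlation|
#' observed across the tested conditioning sets.
#'
#' @param data numeric matrix (n x p) with column names; ignored when a
#'   custom `test` is supplied together with `p_nodes`.
#' @param alpha significance level of the CI test, in (0, 1).
#' @param test optional CI test `function(i, j, S) -> p-value` (e.g. a
#'   d-separation oracle); defaults to [partial_correlation_test()] on
#'   `data`.
#' @param p_nodes number of nodes when `data` is not given.
#' @param max_level cap on conditioning-set size.
#' @return a `network_graph`: `nodes`, logical adjacency `adj`, `sepset`
#'   (list of lists), `strength` matrix of minimal |partial correlation|.
#' @export
pc_skeleton <- function(data = NULL, alpha = 0.01, test = NULL, p_nodes = NULL,
                        max_level = Inf) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(test)) {
    stopifnot(is.matrix(data))
    if (nrow(data) <= ncol(data)) {
      warning("n <= p: partial-correlation tests may be unstable")
    }
    test <- function(i, j, S) partial_correlation_test(data, i, j, S)
    p <- ncol(data)
    nodes <- colnames(data) %||% paste0("V", seq_len(p))
  } else {
    p <- p_nodes %||% ncol(data)
    nodes <- if (!is.null(data)) colnames(data) else paste0("V", seq_len(p))
    nodes <- nodes %||% paste0("V", seq_len(p))
  }
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  sepset <- vector("list", p)
  for (i in seq_len(p)) sepset[[i]] <- vector("list", p)
  strength <- matrix(Inf, p, p)
  level <- 0L
  repeat {
    if (level > max_level) break
    if (max(colSums(adj)) - 1L < level) break
    adj_frozen <- adj
    pairs <- which(upper.tri(adj_frozen) & adj_frozen, arr.ind = TRUE)
    if (nrow(pairs) == 0L) break
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!adj[i, j]) next
      for (anchor in list(c(i, j), c(j, i))) {
        a <- anchor[1]; b <- anchor[2]
        nbrs <- setdiff(which(adj_frozen[a, ]), b)
        if (length(nbrs) < level) next
        subsets <- if (level == 0L) list(integer(0)) else
          combn_sets(nbrs, level)
        if (length(subsets) == 0L) next
        removed <- FALSE
        for (S in subsets) {
          pv <- test(a, b, S)
          pc <- attr(pv, "pcor")
          if (!is.null(pc)) {
            strength[i, j] <- strength[j, i] <- min(strength[i, j], abs(pc))
          }
          if (pv > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepset[[i]][[j]] <- sepset[[j]][[i]] <- S
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
    level <- level + 1L
  }
  strength[!is.finite(strength)] <- NA
  dimnames(adj) <- dimnames(strength) <- list(nodes, nodes)
  structure(list(nodes = nodes, adj = adj, sepset = sepset,
                 strength = strength, alpha = alpha),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d nodes, %d edges (alpha = %g)\n",
              length(x$nodes), sum(x$adj) / 2, x$alpha))
  invisible(x)
}

#' Edge list of a network graph
#' @param g `network_graph`.
#' @return data.frame with `from`, `to`, `min_abs_pcor`.
#' @export
network_edges <- function(g) {
  idx <- which(upper.tri(g$adj) & g$adj, arr.ind = TRUE)
  data.frame(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]],
             min_abs_pcor = g$strength[idx])
}

#' d-separation oracle CI test for a known DAG
#'
#' Returns a test function usable as the `test` argument of
#' [pc_skeleton()]: p-value 1 when `i` and `j` are d-separated given `S` in
#' the supplied DAG, 0 otherwise. d-separation is decided by the
#' moralized-ancestral-graph criterion: restrict to ancestors of
#' `{i, j} union S`, marry co-parents, drop directions, delete `S`, and test
#' connectivity.
#'
#' @param dag_adj p x p logical/0-1 matrix, `dag_adj[a, b]` meaning an edge
#'   a -> b; must be acyclic.
#' @return `function(i, j, S)` returning 0 or 1.
#' @export
dsep_oracle <- function(dag_adj) {
  dag_adj <- dag_adj != 0
  p <- ncol(dag_adj)
  ancestors <- function(nodes) {
    res <- nodes
    frontier <- nodes
    while (length(frontier)) {
      pa <- which(apply(dag_adj[, frontier, drop = FALSE], 1, any))
      frontier <- setdiff(pa, res)
      res <- union(res, frontier)
    }
    res
  }
  function(i, j, S = integer(0)) {
    anc <- ancestors(c(i, j, S))
    sub <- dag_adj[anc, anc, drop = FALSE]
    moral <- sub | t(sub)
    for (child in seq_along(anc)) {         # marry parents of a common child
      pa <- which(sub[, child])
      if (length(pa) > 1) moral[pa, pa] <- TRUE
    }
    diag(moral) <- FALSE
    keep <- !(anc %in% S)
    moral <- moral[keep, keep, drop = FALSE]
    ids <- anc[keep]
    a <- match(i, ids); b <- match(j, ids)
    if (is.na(a) || is.na(b)) return(1)
    reach <- a
    frontier <- a
    while (length(frontier)) {
      nxt <- which(apply(moral[frontier, , drop = FALSE], 2, any))
      frontier <- setdiff(nxt, reach)
      reach <- union(reach, frontier)
      if (b %in% reach) return(0)
    }
    1
  }
}

#' Louvain community detection on a network graph
#'
#' Greedy modularity optimization (node sweeps plus aggregation) on the
#' unweighted skeleton by default; optionally weighted by the recorded
#' |partial correlation| strengths. Deterministic given the seed. An edgeless
#' graph yields singleton clusters with modularity 0; the returned partition
#' never has lower modularity than all-singletons.
#'
#' @param g `network_graph`.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed (required).
#' @param weighted use `min_abs_pcor` edge weights.
#' @return a `cluster_assignment`: named integer `membership` (contiguous
#'   labels) and the partition `modularity`.
#' @export
louvain_clusters <- function(g, resolution = 1, seed, weighted = FALSE) {
  assert_seed(seed)
  stopifnot(inherits(g, "network_graph"))
  p <- length(g$nodes)
  if (p == 0L) stop("graph is empty")
  if (sum(g$adj) == 0) {
    memb <- stats::setNames(seq_len(p), g$nodes)
    return(structure(list(membership = memb, modularity = 0),
                     class = "cluster_assignment"))
  }
  w <- NULL
  A <- g$adj * 1
  if (weighted) A <- A * ifelse(is.na(g$strength), 0, g$strength)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = if (weighted) TRUE else NULL)
  set.seed(seed)
  cl <- igraph::cluster_louvain(ig, resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- stats::setNames(as.integer(factor(memb, levels = unique(memb))),
                          g$nodes)
  mod <- igraph::modularity(ig, memb, resolution = resolution)
  structure(list(membership = memb, modularity = mod),
            class = "cluster_assignment")
}

#' Cluster-specific lipid scores
#'
#' Restricts the score to each cluster's members using the same weights and
#' scaling constant as the full score, so the unscaled cluster scores sum
#' exactly to the unscaled full score.
#'
#' @param m log-scale `lipid_matrix`.
#' @param def `score_definition` (intercept must be 0).
#' @param clusters `cluster_assignment` over (at least) the score variables.
#' @return matrix samples x clusters of per-sample cluster scores.
#' @export
cluster_scores <- function(m, def, clusters) {
  stopifnot(inherits(def, "score_definition"),
            inherits(clusters, "cluster_assignment"))
  if (def$intercept != 0) stop("cluster scores require an intercept-free score")
  miss <- setdiff(def$variables, names(clusters$membership))
  if (length(miss)) {
    stop(sprintf("variables missing from the cluster assignment: %s",
                 paste(miss, collapse = ", ")))
  }
  labs <- clusters$membership[def$variables]
  out <- sapply(sort(unique(labs)), function(k) {
    sub <- subscore(def, def$variables[labs == k], variant = "cluster_score")
    compute_score(m, sub)
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = 1)
  colnames(out) <- paste0("cluster_", sort(unique(labs)))
  rownames(out) <- rownames(m$values)
  out
}

#' Direct-effect classification of network nodes against an outcome
#'
#' For each node, the outcome model is refitted with the node as exposure
#' under every subset of its direct network neighbors added to the base
#' adjustment set. A node is classified `direct` when every submodel is
#' significant with a consistent coefficient sign, `none` when no submodel is
#' significant, and `ambiguous` otherwise. Nodes whose degree exceeds
#' `degree_cap` are flagged `unevaluated` (the submodel loop is exponential
#' in degree). BH-adjusted flags across nodes (on each node's worst-case
#' submodel p-value) are reported alongside.
#'
#' @param g `network_graph` whose nodes are columns of `d`.
#' @param d data.frame holding the node columns plus the outcome-model design
#'   (case-cohort columns and covariates).
#' @param base_covariates character vector of always-included covariates.
#' @param fitter `function(d, exposure, covariates)` returning a list/object
#'   with elements `loghr`/`logor` (coefficient) and `p`; default
#'   [fit_prentice_cox()].
#' @param threshold per-submodel significance threshold (default 0.05).
#' @param degree_cap maximal node degree evaluated (default 12).
#' @return data.frame: `node`, `classification`, `n_models`, `max_p`,
#'   `min_p`, `sign_consistent`, `direct_bh`.
#' @export
netcoupler_classify <- function(g, d, base_covariates = character(0),
                                fitter = fit_prentice_cox, threshold = 0.05,
                                degree_cap = 12L) {
  stopifnot(inherits(g, "network_graph"), all(g$nodes %in% names(d)))
  rows <- lapply(seq_along(g$nodes), function(k) {
    node <- g$nodes[k]
    nbrs <- g$nodes[g$adj[k, ]]
    if (length(nbrs) > degree_cap) {
      return(data.frame(node = node, classification = "unevaluated",
                        n_models = 0L, max_p = NA_real_, min_p = NA_real_,
                        sign_consistent = NA))
    }
    subsets <- list(character(0))
    for (sz in seq_len(length(nbrs))) {
      subsets <- c(subsets, combn_sets(nbrs, sz))
    }
    ps <- signs <- numeric(length(subsets))
    for (si in seq_along(subsets)) {
      fit <- fitter(d, exposure = node,
                    covariates = c(base_covariates, subsets[[si]]))
      co <- fit$loghr %||% fit$logor
      ps[si] <- fit$p
      signs[si] <- sign(co)
    }
    sig <- ps < threshold
    consistent <- length(unique(signs)) == 1L
    cls <- if (all(sig) && consistent) "direct"
           else if (!any(sig)) "none"
           else "ambiguous"
    data.frame(node = node, classification = cls,
               n_models = length(subsets), max_p = max(ps), min_p = min(ps),
               sign_consistent = consistent)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$max_p)
  out$direct_bh <- FALSE
  if (any(ok)) {
    q <- bh_fdr(out$max_p[ok], level = threshold)
    out$direct_bh[ok] <- q$reject & out$classification[ok] == "direct"
  }
  out
}

#' Write a network graph as an edge-list TSV and GraphML
#'
#' @param g `network_graph`.
#' @param path base path; writes `<path>.tsv` and `<path>.graphml`.
#' @return invisible vector of paths written.
#' @export
write_network <- function(g, path) {
  edges <- network_edges(g)
  tsv <- paste0(path, ".tsv")
  utils::write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ig <- igraph::graph_from_adjacency_matrix(g$adj * 1, mode = "undirected")
  gml <- paste0(path, ".graphml")
  igraph::write_graph(ig, gml, format = "graphml")
  invisible(c(tsv, gml))
}
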