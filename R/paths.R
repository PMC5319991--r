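#' Prediction configuration
#'
#' Bundles the tunable parameters of the path-based predictor.
#'
#' @param L maximum path length in edges (integer >= 1). Default 3: with
#'   similarity weights in (0, 1] and an exponential length decay, paths
#'   longer than three edges contribute negligibly while the enumeration
#'   cost grows geometrically.
#' @param alpha decay coefficient (> 0) in the path score
#'   `S(p) = (prod of edge weights)^(alpha * length)`. Default 2.26,
#'   mirroring the published path-based association models of the same
#'   family; robustness to this choice is exercised in the test suite.
#' @param threshold similarity-edge cutoff `T` in `[0, 1]`. Default 0
#'   keeps every similarity edge, the only default that cannot silently
#'   discard relevant paths; runtime is controlled by `L` instead.
#' @param gamma_microbe,gamma_disease GIP bandwidth scales (gamma-prime),
#'   default 1 on both axes.
#' @return a `pmda_config` list.
#' @export
pmda_config <- function(L = 3L, alpha = 2.26, threshold = 0,
                        gamma_microbe = 1, gamma_disease = 1) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be an integer >= 1")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]")
  }
  for (g in c(gamma_microbe, gamma_disease)) {
    if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0) {
      stop("gamma scales must be single non-negative numbers")
    }
  }
  structure(list(L = L, alpha = alpha, threshold = threshold,
                 gamma_microbe = gamma_microbe,
                 gamma_disease = gamma_disease),
            class = "pmda_config")
}

#' @export
print.pmda_config <- function(x, ...) {
  cat(sprintf("pathmda config: L = %d, alpha = %g, T = %g, gamma' (microbe, disease) = (%g, %g)\n",
              x$L, x$alpha, x$threshold, x$gamma_microbe, x$gamma_disease))
  invisible(x)
}

#' Enumerate all simple paths between a microbe and a disease
#'
#' Recursive depth-first search over the heterogeneous network: visited
#' nodes are marked on entry and unmarked on backtrack, so every returned
#' path is cycle-free (no repeated nodes). Paths start at the microbe, end
#' at the disease, may traverse nodes of either type in any order, and have
#' at most `L` edges. Neighbours are expanded in ascending node order, so
#' paths are produced in a fixed lexicographic order.
#'
#' @param net a `hetnet` object.
#' @param microbe microbe name or position.
#' @param disease disease name or position.
#' @param L maximum number of edges per path (>= 1).
#' @return a list of `mda_path` objects, each a list with `names` (typed
#'   node labels), `weights` (edge weights along the path) and `length`
#'   (edge count).
#' @export
enumerate_paths <- function(net, microbe, disease, L = 3L) {
  if (!inherits(net, "hetnet")) stop("net must be a hetnet object")
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be an integer >= 1")
  s <- node_index(net, microbe, "microbe")
  t <- node_index(net, disease, "disease")
  n <- net$n_microbes + net$n_diseases
  labels <- c(paste0("microbe:", net$microbe_names),
              paste0("disease:", net$disease_names))
  W <- net$W
  adj <- net$adj
  visited <- logical(n)
  visited[s] <- TRUE
  acc <- list()
  count <- 0L
  record <- function(nodes, weights) {
    count <<- count + 1L
    acc[[count]] <<- structure(
      list(names = labels[nodes], weights = weights,
           length = length(weights)),
      class = "mda_path")
  }
  # `used` = edges consumed to reach v; a path is recorded as soon as the
  # target is a neighbour, and the search never expands through the target
  # (a simple path cannot leave its endpoint and return).
  dfs <- function(v, nodes, weights, used) {
    for (u in adj[[v]]) {
      if (visited[u]) next
      w <- W[v, u]
      if (u == t) {
        record(c(nodes, u), c(weights, w))
      } else if (used + 1L < L) {
        visited[u] <<- TRUE
        dfs(u, c(nodes, u), c(weights, w), used + 1L)
        visited[u] <<- FALSE
      }
    }
  }
  dfs(s, s, numeric(0L), 0L)
  acc[seq_len(count)]
}

#' @export
print.mda_path <- function(x, ...) {
  cat(paste(x$names, collapse = " -- "),
      sprintf(" [weights: %s]\n", paste(signif(x$weights, 6), collapse = ", ")))
  invisible(x)
}

#' Score a single path with exponential length decay
#'
#' `S(p) = (product of edge weights) ^ (alpha * length)`. Since every edge
#' weight lies in (0, 1], longer paths and weaker edges are both penalised;
#' a direct known-association edge (weight 1) scores exactly 1.
#'
#' @param path an `mda_path` object, or a bare numeric vector of edge
#'   weights.
#' @param alpha decay coefficient (> 0).
#' @return the path score, in `[0, 1]`.
#' @export
path_score <- function(path, alpha = 2.26) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  weights <- if (inherits(path, "mda_path")) path$weights else as.numeric(path)
  if (length(weights) == 0L) stop("a path must have at least one edge")
  if (any(weights <= 0 | weights > 1)) stop("edge weights must lie in (0, 1]")
  prod(weights)^(alpha * length(weights))
}

#' Total association score of one microbe-disease pair
#'
#' Aggregates the scores of all simple paths of at most `L` edges between
#' the pair: the sum of [path_score()] over [enumerate_paths()], in the
#' DFS's fixed lexicographic path order. A disconnected pair scores 0.
#'
#' @inheritParams enumerate_paths
#' @param alpha decay coefficient.
#' @return a non-negative scalar.
#' @export
total_score <- function(net, microbe, disease, L = 3L, alpha = 2.26) {
  paths <- enumerate_paths(net, microbe, disease, L)
  if (length(paths) == 0L) return(0)
  sum(vapply(paths, path_score, numeric(1L), alpha = alpha))
}

# Exact closed form for the weighted simple-path sums with L <= 3.
#
# For each length l the decayed score of a path is the product of the
# elementwise powers w^(alpha*l) along its edges, so the sum over length-l
# walks is an entry of the l-th matrix power of B_l = W^(alpha*l). With a
# zero diagonal, all length-1 and length-2 walks between distinct endpoints
# are already simple; length-3 walks a-u-v-b are non-simple exactly when
# u = b or v = a, removed by inclusion-exclusion:
#   simple3 = B^3 - B * (diag2[a] + diag2[b]) + B^3(elementwise)
# where diag2 = diag(B %*% B).
score_closed_form <- function(W, nm, nd, L, alpha) {
  mi <- seq_len(nm)
  di <- nm + seq_len(nd)
  A <- W^alpha
  TS <- A[mi, di, drop = FALSE]
  if (L >= 2L) {
    B2 <- W^(2 * alpha)
    TS <- TS + (B2 %*% B2)[mi, di, drop = FALSE]
  }
  if (L >= 3L) {
    B <- W^(3 * alpha)
    Bsq <- B %*% B
    B3 <- Bsq %*% B
    d2 <- diag(Bsq)
    S3 <- B3 - B * outer(d2, d2, `+`) + B^3
    TS <- TS + S3[mi, di, drop = FALSE]
  }
  TS
}

#' Predict scores for every microbe-disease pair
#'
#' The full pipeline: computes the microbe and disease GIP kernels from
#' `Y`, assembles the heterogeneous network at threshold `T`, and fills the
#' total association score for every pair, including known ones (filtering
#' known pairs out of candidate rankings is an evaluation concern). For
#' `L <= 3` the simple-path sums are computed in an exact closed form from
#' powers of the weighted adjacency matrix; for larger `L` each pair is
#' scored by depth-first enumeration. Both routes produce identical results
#' up to floating-point round-off, and repeated runs are bit-identical.
#'
#' @param Y an `mda_assoc` matrix.
#' @param config a [pmda_config()] list.
#' @return an `mda_scores` matrix (`nm x nd`, non-negative, named like
#'   `Y`), with the configuration recorded in attribute `params`.
#' @examples
#' Y <- association_matrix(rbind(c(1, 0), c(1, 1)),
#'                         c("m1", "m2"), c("d1", "d2"))
#' predict_associations(Y, pmda_config(L = 2, alpha = 1))
#' @export
predict_associations <- function(Y, config = pmda_config()) {
  Y <- as_assoc(Y)
  if (!inherits(config, "pmda_config")) stop("config must be a pmda_config object")
  net <- build_hetnet(Y, threshold = config$threshold,
                      gamma_microbe = config$gamma_microbe,
                      gamma_disease = config$gamma_disease)
  nm <- net$n_microbes
  nd <- net$n_diseases
  if (config$L <= 3L) {
    TS <- score_closed_form(net$W, nm, nd, config$L, config$alpha)
  } else {
    TS <- matrix(0, nm, nd)
    for (j in seq_len(nd)) {
      for (i in seq_len(nm)) {
        TS[i, j] <- total_score(net, i, j, config$L, config$alpha)
      }
    }
  }
  dimnames(TS) <- dimnames(Y)
  structure(TS, params = config, class = c("mda_scores", "matrix", "array"))
}

#' @export
print.mda_scores <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("prediction scores: %d microbes x %d diseases (L = %d, alpha = %g, T = %g)\n",
              nrow(x), ncol(x), p$L, p$alpha, p$threshold))
  invisible(x)
}
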