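# Independent oracles: naive per-pair kernel evaluation and permutation
# brute-force path enumeration. Deliberately loop-based / grid-based so
# they share no code path with the package implementation.

# Elementwise double-loop evaluation of the GIP kernel.
naive_gip <- function(Y, axis, gamma_prime = 1) {
  profiles <- if (axis == "disease") {
    lapply(seq_len(ncol(Y)), function(j) as.numeric(Y[, j]))
  } else {
    lapply(seq_len(nrow(Y)), function(i) as.numeric(Y[i, ]))
  }
  n <- length(profiles)
  norms <- vapply(profiles, function(p) sum(p^2), numeric(1))
  gamma <- gamma_prime / (sum(norms) / n)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-gamma * sum((profiles[[i]] - profiles[[j]])^2))
    }
  }
  K
}

# All simple paths from s to t with <= L edges, by exhaustive enumeration
# of intermediate-node tuples (expand.grid over node indices).
brute_paths <- function(W, s, t, L) {
  n <- nrow(W)
  out <- character(0)
  if (W[s, t] > 0) out <- paste(s, t, sep = "-")
  for (l in 2:max(2L, L)) {
    if (l > L) break
    mids <- as.matrix(expand.grid(rep(list(seq_len(n)), l - 1L)))
    for (r in seq_len(nrow(mids))) {
      v <- mids[r, ]
      seqn <- c(s, v, t)
      if (anyDuplicated(seqn)) next
      wts <- W[cbind(seqn[-length(seqn)], seqn[-1L])]
      if (all(wts > 0)) out <- c(out, paste(seqn, collapse = "-"))
    }
  }
  sort(out)
}

# Sum of decayed path scores over the brute-force path set.
brute_total <- function(W, s, t, L, alpha) {
  sigs <- brute_paths(W, s, t, L)
  if (length(sigs) == 0L) return(0)
  total <- 0
  for (sig in sigs) {
    seqn <- as.integer(strsplit(sig, "-", fixed = TRUE)[[1L]])
    wts <- W[cbind(seqn[-length(seqn)], seqn[-1L])]
    total <- total + prod(wts)^(alpha * length(wts))
  }
  total
}

# Canonical signature of a DFS path list, comparable with brute_paths().
dfs_path_signatures <- function(net, paths) {
  labels <- c(paste0("microbe:", net$microbe_names),
              paste0("disease:", net$disease_names))
  sort(vapply(paths, function(p) {
    paste(match(p$names, labels), collapse = "-")
  }, character(1)))
}
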