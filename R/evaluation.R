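# Cross-validation protocols with leakage-safe kernel recomputation.
#
# All three protocols share one mechanic: held-out known associations are
# zeroed in Y, the GIP kernels, network and score matrix are recomputed
# from the reduced matrix (so test information never enters the similarity
# matrices), and each held-out pair is ranked among candidate pairs by
# descending score with mid-rank tie handling.

# Mid-rank of a test score among itself plus a candidate score vector.
midrank <- function(score, candidates) {
  sum(candidates > score) + sum(candidates == score) / 2 + 1
}

new_cv_report <- function(protocol, auc, roc_points, ranks, config,
                          auc_sd = NA_real_, seed = NA_integer_,
                          per_repeat_auc = NULL) {
  structure(list(protocol = protocol, auc = auc, auc_sd = auc_sd,
                 roc_points = roc_points, ranks = ranks, seed = seed,
                 per_repeat_auc = per_repeat_auc, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d test associations, AUC = %.4f%s\n",
              x$protocol, nrow(x$ranks), x$auc,
              if (is.finite(x$auc_sd)) sprintf(" +/- %.4f (sd over repeats)", x$auc_sd) else ""))
  invisible(x)
}

#' ROC curve and AUC from per-test rank records
#'
#' Each positive test sample is summarised by its rank `r` among `n + 1`
#' items (itself plus its `n` non-positive candidates). Because candidate
#' sets can differ in size across tests (local LOOCV ranks within one
#' disease), the normalised rank `u = (r - 1) / n` -- the fraction of
#' candidates scoring above the positive -- is pooled across tests and the
#' acceptance threshold is swept over `[0, 1]`: at threshold `t`,
#' sensitivity is the fraction of positives with `u <= t` and the false
#' positive rate is the mean fraction of candidates accepted, which is `t`.
#' The AUC, integrated exactly over the resulting staircase, is
#' `1 - mean(u)`; when all candidate sets coincide this equals the
#' Mann-Whitney rank-sum statistic with mid-rank tie correction.
#'
#' @param ranks data frame with numeric columns `rank` (mid-ranks allowed)
#'   and `n_candidates`.
#' @return a list with `auc`, `roc_points` (data frame of `fpr`, `tpr`
#'   staircase vertices from (0,0) to (1,1)) and `normalized_ranks`.
#' @export
roc_from_ranks <- function(ranks) {
  if (!is.data.frame(ranks) || nrow(ranks) == 0L) {
    stop("ranks must be a non-empty data frame")
  }
  r <- ranks$rank
  n <- ranks$n_candidates
  if (any(is.na(r)) || any(r < 1) || any(r > n + 1)) {
    stop("each rank must lie in [1, n_candidates + 1]")
  }
  u <- (r - 1) / n
  th <- sort(unique(c(0, u, 1)))
  fpr <- numeric(0L)
  tpr <- numeric(0L)
  prev <- 0
  for (t in th) {
    f <- mean(u <= t)
    fpr <- c(fpr, t)
    tpr <- c(tpr, prev)
    if (f > prev) {
      fpr <- c(fpr, t)
      tpr <- c(tpr, f)
      prev <- f
    }
  }
  list(auc = 1 - mean(u),
       roc_points = data.frame(fpr = fpr, tpr = tpr),
       normalized_ranks = u)
}

# Shared engine: score one training matrix and rank the given held-out
# pairs. `candidate_cells` is the fixed global candidate set (linear
# indices of the original zero cells); for local mode candidates are the
# test disease's unconfirmed microbes in the original matrix.
rank_held_out <- function(Y, Ytr, held, config, mode) {
  TS <- predict_associations(Ytr, config)
  ind <- arrayInd(held, dim(Y))
  zero_global <- if (mode == "global") TS[unclass(Y) == 0] else NULL
  out <- vector("list", length(held))
  for (k in seq_along(held)) {
    i <- ind[k, 1L]
    j <- ind[k, 2L]
    s <- TS[i, j]
    cand <- if (mode == "global") zero_global else TS[Y[, j] == 0, j]
    out[[k]] <- data.frame(
      microbe = rownames(Y)[i], disease = colnames(Y)[j],
      score = s, rank = midrank(s, cand), n_candidates = length(cand),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Leave-one-out cross-validation (global or local)
#'
#' Each known association is removed in turn; the GIP kernels, network and
#' scores are recomputed from the reduced matrix; and the held-out pair is
#' ranked among candidates by its recomputed score. In `global` mode the
#' candidate set is every unverified pair of the original matrix (shared
#' across test rounds); in `local` mode it is only the test disease's
#' unconfirmed microbes. Both protocols are deterministic.
#'
#' @param Y an `mda_assoc` matrix with at least 2 known associations.
#' @param config a [pmda_config()] list.
#' @param mode `"global"` or `"local"`.
#' @param test_pairs optional integer subset of the known-pair list
#'   (column-major order) to evaluate, e.g. for a single-round smoke run;
#'   default all.
#' @return a `cv_report`: protocol, AUC, ROC staircase, and per-test rank
#'   records.
#' @export
loocv <- function(Y, config = pmda_config(), mode = c("global", "local"),
                  test_pairs = NULL) {
  Y <- as_assoc(Y)
  mode <- match.arg(mode)
  known <- which(unclass(Y) == 1)
  if (length(known) < 2L) stop("LOOCV needs at least 2 known associations")
  if (!is.null(test_pairs)) {
    test_pairs <- as.integer(test_pairs)
    if (any(is.na(test_pairs)) || any(test_pairs < 1L) ||
        any(test_pairs > length(known))) {
      stop("test_pairs must index the known-association list")
    }
    known <- known[test_pairs]
  }
  records <- vector("list", length(known))
  for (k in seq_along(known)) {
    Ytr <- Y
    Ytr[known[k]] <- 0
    records[[k]] <- rank_held_out(Y, Ytr, known[k], config, mode)
  }
  ranks <- do.call(rbind, records)
  roc <- roc_from_ranks(ranks)
  new_cv_report(paste0(mode, "_loocv"), roc$auc, roc$roc_points, ranks, config)
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are randomly partitioned into `k`
#' disjoint folds of near-equal size (differing by at most one). Each fold
#' is held out in turn: all its pairs are zeroed together, kernels, network
#' and scores are recomputed once per fold, and every held-out pair is
#' ranked among the unverified pairs of the original matrix (global-style
#' candidate set). A per-repeat AUC is computed from the repeat's pooled
#' rank records; the report carries their mean and standard deviation plus
#' a ROC built from all records. Fully reproducible from `seed`. With `k`
#' equal to the number of known pairs, the partition degenerates to
#' leave-one-out and the mean AUC equals the global LOOCV AUC.
#'
#' @inheritParams loocv
#' @param k number of folds (>= 2, at most the number of known pairs).
#' @param repeats number of random re-partitions (default 100).
#' @param seed RNG seed driving the fold assignments.
#' @return a `cv_report` with `auc` (mean over repeats), `auc_sd`,
#'   `per_repeat_auc`, pooled `roc_points` and rank records.
#' @export
kfold_cv <- function(Y, k = 5L, repeats = 100L, seed = 1L,
                     config = pmda_config()) {
  Y <- as_assoc(Y)
  k <- as.integer(k)
  repeats <- as.integer(repeats)
  known <- which(unclass(Y) == 1)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (length(known) < k) stop("fewer known associations than folds")
  if (is.na(repeats) || repeats < 1L) stop("repeats must be an integer >= 1")
  fold_template <- rep(seq_len(k), length.out = length(known))
  all_records <- vector("list", repeats)
  aucs <- numeric(repeats)
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      fold_of <- integer(length(known))
      fold_of[sample.int(length(known))] <- fold_template
      rep_records <- vector("list", k)
      for (f in seq_len(k)) {
        held <- known[fold_of == f]
        Ytr <- Y
        Ytr[held] <- 0
        rep_records[[f]] <- rank_held_out(Y, Ytr, held, config, "global")
      }
      rep_ranks <- do.call(rbind, rep_records)
      rep_ranks$repeat_id <- rep_i
      aucs[rep_i] <- roc_from_ranks(rep_ranks)$auc
      all_records[[rep_i]] <- rep_ranks
    }
  })
  ranks <- do.call(rbind, all_records)
  roc <- roc_from_ranks(ranks)
  new_cv_report("kfold", mean(aucs), roc$roc_points, ranks, config,
                auc_sd = stats::sd(aucs), seed = as.integer(seed),
                per_repeat_auc = aucs)
}

#' Serialise a cross-validation report as JSON
#'
#' Writes protocol, AUC (and sd over repeats where applicable), ROC
#' staircase points, per-test rank records and the full effective
#' configuration, so every reported AUC carries its (L, alpha, T)
#' provenance.
#'
#' @param report a `cv_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  if (!inherits(report, "cv_report")) stop("report must be a cv_report")
  payload <- list(
    protocol = report$protocol,
    auc = report$auc,
    auc_sd = report$auc_sd,
    n_tests = nrow(report$ranks),
    seed = report$seed,
    config = unclass(report$config),
    per_repeat_auc = report$per_repeat_auc,
    roc_points = report$roc_points,
    ranks = report$ranks
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
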