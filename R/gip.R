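#' Interaction profile of a microbe or disease
#'
#' The interaction profile of a disease is the binary vector recording which
#' microbes it is associated with (a column of `Y`); the profile of a
#' microbe is the corresponding row. Profiles are the inputs of the Gaussian
#' interaction profile (GIP) kernel.
#'
#' @param Y an `mda_assoc` matrix.
#' @param axis `"disease"` or `"microbe"`.
#' @param index node position (integer) or name (character) on that axis.
#' @return a named binary vector: length `nm` for a disease profile, `nd`
#'   for a microbe profile.
#' @export
interaction_profile <- function(Y, axis = c("disease", "microbe"), index) {
  Y <- as_assoc(Y)
  axis <- match.arg(axis)
  registry <- if (axis == "disease") colnames(Y) else rownames(Y)
  if (is.character(index)) {
    i <- match(index, registry)
    if (is.na(i)) stop(sprintf("unknown %s: '%s'", axis, index))
  } else {
    i <- as.integer(index)
    if (is.na(i) || i < 1L || i > length(registry)) {
      stop(sprintf("%s index out of range: %s (valid 1..%d)",
                   axis, index, length(registry)))
    }
  }
  if (axis == "disease") Y[, i] else Y[i, ]
}

#' Effective GIP kernel bandwidth
#'
#' The kernel bandwidth gamma is obtained by normalising the user-set
#' gamma-prime by the mean squared Euclidean norm of the axis's interaction
#' profiles. For binary profiles the squared norm is the association count,
#' so the denominator is the average number of associations per node on
#' that axis; the counts are accumulated as integers before the single
#' division, making the result exactly reproducible.
#'
#' @inheritParams interaction_profile
#' @param gamma_prime non-negative bandwidth scale, default 1.
#' @return the effective bandwidth gamma (a positive scalar; 0 when
#'   `gamma_prime = 0`).
#' @export
gip_bandwidth <- function(Y, axis = c("disease", "microbe"), gamma_prime = 1) {
  Y <- as_assoc(Y)
  axis <- match.arg(axis)
  if (!is.numeric(gamma_prime) || length(gamma_prime) != 1L || gamma_prime < 0) {
    stop("gamma_prime must be a single non-negative number")
  }
  counts <- if (axis == "disease") colSums(Y) else rowSums(Y)
  total <- sum(counts)
  if (total == 0) {
    stop("all interaction profiles on this axis are zero: the GIP kernel bandwidth is undefined on an empty association network")
  }
  gamma_prime * length(counts) / total
}

#' Gaussian interaction profile kernel similarity matrix
#'
#' Computes `K[i, j] = exp(-gamma * ||IP(i) - IP(j)||^2)` over all node
#' pairs on one axis, with the bandwidth from [gip_bandwidth()]. Similar
#' diseases share microbes (and vice versa), so nodes with overlapping
#' profiles receive similarity close to 1; the diagonal is exactly 1.
#' Squared distances between binary profiles are assembled from integer
#' association counts (`||a - b||^2 = |a| + |b| - 2 a.b`), so the matrix is
#' exactly symmetric.
#'
#' @inheritParams gip_bandwidth
#' @return a `gip_kernel` matrix: symmetric, unit diagonal, entries in
#'   (0, 1], with attributes `bandwidth` (effective gamma), `gamma_prime`
#'   and `axis`.
#' @examples
#' Y <- association_matrix(diag(2), c("m1", "m2"), c("d1", "d2"))
#' gip_kernel(Y, "disease")[1, 2]  # exp(-2)
#' @export
gip_kernel <- function(Y, axis = c("disease", "microbe"), gamma_prime = 1) {
  Y <- as_assoc(Y)
  axis <- match.arg(axis)
  gamma <- gip_bandwidth(Y, axis, gamma_prime)
  if (axis == "disease") {
    counts <- colSums(Y)
    gram <- crossprod(unclass(Y))        # t(Y) %*% Y, disease x disease
    nms <- colnames(Y)
  } else {
    counts <- rowSums(Y)
    gram <- tcrossprod(unclass(Y))       # Y %*% t(Y), microbe x microbe
    nms <- rownames(Y)
  }
  dist2 <- outer(counts, counts, `+`) - 2 * gram
  K <- exp(-gamma * dist2)
  diag(K) <- 1
  dimnames(K) <- list(nms, nms)
  structure(K, bandwidth = gamma, gamma_prime = gamma_prime, axis = axis,
            class = c("gip_kernel", "matrix", "array"))
}

#' Write a kernel similarity matrix as a square TSV
#'
#' Inspection export: a square tab-separated table with name headers on both
#' axes. Not consumed by any downstream step.
#'
#' @param K a `gip_kernel` matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(K, path) {
  if (!inherits(K, "gip_kernel")) stop("K must be a gip_kernel matrix")
  utils::write.table(as.data.frame(unclass(K)), path, sep = "\t",
                     quote = FALSE, col.names = NA, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}
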