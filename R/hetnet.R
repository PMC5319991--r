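#' Build the heterogeneous microbe-disease network
#'
#' Assembles one undirected weighted graph over all microbes and diseases
#' from three relations: microbe-disease edges of weight exactly 1 where
#' `Y = 1`; microbe-microbe edges weighted by the microbe GIP kernel; and
#' disease-disease edges weighted by the disease GIP kernel. Similarity
#' edges with weight below the threshold `T` are dropped (`>= T` keeps the
#' edge, so equality survives); association edges have weight 1 and are
#' never removed by any valid threshold. Self-similarity is never
#' materialised as an edge.
#'
#' @param Y an `mda_assoc` matrix.
#' @param KM,KD optional precomputed `gip_kernel` matrices for microbes and
#'   diseases; computed from `Y` when `NULL`.
#' @param threshold similarity cutoff `T` in `[0, 1]`; default 0 keeps all
#'   similarity edges.
#' @param gamma_microbe,gamma_disease bandwidth scales used when kernels
#'   are computed here.
#' @return a `hetnet` object: list with the combined weighted adjacency
#'   matrix `W` (microbes first, then diseases), node registries, the
#'   threshold, and precomputed neighbour lists for path search.
#' @export
build_hetnet <- function(Y, KM = NULL, KD = NULL, threshold = 0,
                         gamma_microbe = 1, gamma_disease = 1) {
  Y <- as_assoc(Y)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]")
  }
  nm <- nrow(Y)
  nd <- ncol(Y)
  if (is.null(KM)) KM <- gip_kernel(Y, "microbe", gamma_microbe)
  if (is.null(KD)) KD <- gip_kernel(Y, "disease", gamma_disease)
  if (!identical(dim(KM), c(nm, nm))) {
    stop(sprintf("microbe kernel is %dx%d but Y has %d microbes",
                 nrow(KM), ncol(KM), nm))
  }
  if (!identical(dim(KD), c(nd, nd))) {
    stop(sprintf("disease kernel is %dx%d but Y has %d diseases",
                 nrow(KD), ncol(KD), nd))
  }
  n <- nm + nd
  W <- matrix(0, n, n)
  mm <- unclass(KM)
  mm[mm < threshold] <- 0
  diag(mm) <- 0
  dd <- unclass(KD)
  dd[dd < threshold] <- 0
  diag(dd) <- 0
  mi <- seq_len(nm)
  di <- nm + seq_len(nd)
  W[mi, mi] <- mm
  W[di, di] <- dd
  W[mi, di] <- unclass(Y)
  W[di, mi] <- t(unclass(Y))
  adj <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
  structure(list(W = W, n_microbes = nm, n_diseases = nd,
                 microbe_names = rownames(Y), disease_names = colnames(Y),
                 threshold = threshold, adj = adj),
            class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("heterogeneous network: %d microbes + %d diseases, %d edges (threshold T = %g)\n",
              x$n_microbes, x$n_diseases, ne, x$threshold))
  invisible(x)
}

#' List the edges of a heterogeneous network
#'
#' @param net a `hetnet` object.
#' @return a data frame with columns `node_a`, `node_b`, `relation`
#'   (`"md"`, `"mm"` or `"dd"`) and `weight`, one row per undirected edge.
#' @export
hetnet_edges <- function(net) {
  if (!inherits(net, "hetnet")) stop("net must be a hetnet object")
  n <- net$n_microbes + net$n_diseases
  ut <- which(upper.tri(net$W) & net$W > 0, arr.ind = TRUE)
  labels <- c(net$microbe_names, net$disease_names)
  types <- rep(c("m", "d"), c(net$n_microbes, net$n_diseases))
  rel <- paste0(types[ut[, 1L]], types[ut[, 2L]])
  rel[rel == "dm"] <- "md"
  data.frame(node_a = labels[ut[, 1L]],
             node_b = labels[ut[, 2L]],
             relation = rel,
             weight = net$W[ut],
             stringsAsFactors = FALSE)
}

# Resolve a microbe or disease name/position to a combined node index.
node_index <- function(net, name, type = c("microbe", "disease")) {
  type <- match.arg(type)
  registry <- if (type == "microbe") net$microbe_names else net$disease_names
  offset <- if (type == "microbe") 0L else net$n_microbes
  if (is.character(name)) {
    i <- match(name, registry)
    if (is.na(i)) stop(sprintf("unknown %s: '%s'", type, name))
  } else {
    i <- as.integer(name)
    if (is.na(i) || i < 1L || i > length(registry)) {
      stop(sprintf("%s index out of range: %s", type, name))
    }
  }
  offset + i
}
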