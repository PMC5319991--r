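# Small programmatic fixtures shared across test files.

# Random binary association matrix with at least one association.
random_assoc <- function(nm, nd, p = 0.5, seed = 1) {
  set.seed(seed)
  Y <- matrix(stats::rbinom(nm * nd, 1L, p), nm, nd)
  if (sum(Y) == 0) Y[1L, 1L] <- 1
  association_matrix(Y, paste0("m", seq_len(nm)), paste0("d", seq_len(nd)))
}

# Write association pairs to a temp file and return the path.
write_pairs <- function(lines, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  writeLines(gsub(" ", sep, lines, fixed = TRUE), path)
  path
}

# The 3-node worked example: m1-d1 (1.0), m1-m2 (0.5), m2-d1 (1.0).
toy_net <- function() {
  Y <- association_matrix(rbind(1, 1), c("m1", "m2"), "d1")
  KM <- structure(matrix(c(1, 0.5, 0.5, 1), 2, 2,
                         dimnames = list(c("m1", "m2"), c("m1", "m2"))),
                  bandwidth = 1, gamma_prime = 1, axis = "microbe",
                  class = c("gip_kernel", "matrix", "array"))
  KD <- structure(matrix(1, 1, 1, dimnames = list("d1", "d1")),
                  bandwidth = 1, gamma_prime = 1, axis = "disease",
                  class = c("gip_kernel", "matrix", "array"))
  build_hetnet(Y, KM, KD, threshold = 0)
}
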