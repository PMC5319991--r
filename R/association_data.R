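#' Construct a binary microbe-disease association matrix
#'
#' The association matrix `Y` is the central input of the predictor: a binary
#' `nm x nd` matrix with one row per microbe and one column per disease,
#' where `Y[i, j] = 1` records a curated association between microbe `i` and
#' disease `j`. Row and column names act as stable registries; all
#' user-facing output refers to nodes by name.
#'
#' @param values numeric matrix of 0/1 entries, microbes in rows, diseases
#'   in columns.
#' @param microbe_names character vector of unique microbe names (defaults
#'   to `rownames(values)`).
#' @param disease_names character vector of unique disease names (defaults
#'   to `colnames(values)`).
#' @return an object of class `mda_assoc`: the validated matrix with name
#'   registries attached as dimnames.
#' @examples
#' Y <- association_matrix(rbind(c(1, 0), c(1, 1)),
#'                         c("m1", "m2"), c("d1", "d2"))
#' sum(Y)  # 3 known associations
#' @export
association_matrix <- function(values, microbe_names = rownames(values),
                               disease_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(microbe_names) || is.null(disease_names)) {
    stop("microbe and disease name registries are required")
  }
  microbe_names <- as.character(microbe_names)
  disease_names <- as.character(disease_names)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("association matrix needs at least one microbe and one disease")
  }
  if (length(microbe_names) != nrow(values) ||
      length(disease_names) != ncol(values)) {
    stop("name registries do not match matrix dimensions")
  }
  if (anyDuplicated(microbe_names)) stop("duplicate microbe names in registry")
  if (anyDuplicated(disease_names)) stop("duplicate disease names in registry")
  if (anyNA(values) || !all(values == 0 | values == 1)) {
    stop("association matrix entries must be exactly 0 or 1")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(microbe_names, disease_names)
  class(values) <- c("mda_assoc", "matrix", "array")
  values
}

# Coerce a plain named binary matrix, passing mda_assoc objects through.
as_assoc <- function(Y) {
  if (inherits(Y, "mda_assoc")) return(Y)
  association_matrix(Y)
}

#' @export
print.mda_assoc <- function(x, ...) {
  cat(sprintf("microbe-disease association matrix: %d microbes x %d diseases, %d associations (density %.4f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  invisible(x)
}

#' Read a microbe-disease association list
#'
#' Parses a two-column text file (HMDAD-style export) with one
#' `microbe<sep>disease` pair per line into an [association_matrix()].
#' Lines starting with `#` and blank lines are skipped. Names are trimmed of
#' surrounding whitespace and matched case-sensitively; every distinct name
#' string is a distinct node (no taxonomic normalisation is attempted).
#' Registry order is first-appearance order in the file.
#'
#' A header line is detected (when `header = "auto"`) if neither of the
#' first line's two fields reappears anywhere else in the file. Files
#' written by [write_associations()] always carry a `microbe<TAB>disease`
#' header, so their round trip is exact; for headerless files whose first
#' pair happens to be globally unique, pass `header = "no"`.
#'
#' @param path path to the file, or `"-"` for standard input.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the first data line.
#' @param dedupe collapse repeated pairs to a single 1 (default). With
#'   `dedupe = FALSE` a repeated pair is an error.
#' @param header `"auto"`, `"yes"` or `"no"`.
#' @return an `mda_assoc` matrix; `Y[i, j] = 1` iff the pair occurs in the
#'   file. The unique pair list, in file order, is kept as attribute
#'   `pair_order` so writing reproduces the input ordering.
#' @export
read_associations <- function(path, sep = NULL, dedupe = TRUE,
                              header = c("auto", "yes", "no")) {
  header <- match.arg(header)
  if (identical(path, "-")) {
    lines <- readLines(file("stdin"), warn = FALSE)
  } else {
    if (!file.exists(path)) stop("input file not found: ", path)
    lines <- readLines(path, warn = FALSE)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  lineno <- which(keep)
  if (length(rows) == 0L) stop("no association records found in input")
  if (is.null(sep)) sep <- if (grepl("\t", rows[[1L]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(rows, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("parse error at line %d: expected 2 fields separated by '%s', found %d",
                 lineno[bad], sep, nf[bad]))
  }
  m <- trimws(vapply(fields, `[[`, character(1L), 1L))
  d <- trimws(vapply(fields, `[[`, character(1L), 2L))
  if (any(m == "" | d == "")) {
    bad <- which(m == "" | d == "")[1L]
    stop(sprintf("parse error at line %d: empty name field", lineno[bad]))
  }
  drop_first <- switch(header,
    yes = TRUE,
    no = FALSE,
    auto = length(m) > 1L && !(m[1L] %in% m[-1L]) && !(d[1L] %in% d[-1L])
  )
  if (drop_first) {
    m <- m[-1L]
    d <- d[-1L]
    if (length(m) == 0L) stop("no association records after header line")
  }
  key <- paste(m, d, sep = "\r")
  if (anyDuplicated(key)) {
    if (!dedupe) {
      stop("duplicate association pairs in input (set dedupe = TRUE to collapse them)")
    }
    first <- !duplicated(key)
    m <- m[first]
    d <- d[first]
  }
  microbes <- unique(m)
  diseases <- unique(d)
  Y <- matrix(0, length(microbes), length(diseases))
  Y[cbind(match(m, microbes), match(d, diseases))] <- 1
  out <- association_matrix(Y, microbes, diseases)
  attr(out, "pair_order") <- data.frame(microbe = m, disease = d,
                                        stringsAsFactors = FALSE)
  out
}

#' Write an association matrix as a two-column pair list
#'
#' Emits one `microbe<sep>disease` line per association, preceded by a
#' `microbe<sep>disease` header, UTF-8 encoded with `\n` line endings. Pairs
#' are written in the order recorded at load time when available (attribute
#' `pair_order`), otherwise in row-major matrix order.
#'
#' @param Y an `mda_assoc` matrix.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_associations <- function(Y, path, sep = "\t") {
  Y <- as_assoc(Y)
  po <- attr(Y, "pair_order")
  if (is.null(po)) {
    ind <- which(Y == 1, arr.ind = TRUE)
    ord <- order(ind[, 1L], ind[, 2L])
    po <- data.frame(microbe = rownames(Y)[ind[ord, 1L]],
                     disease = colnames(Y)[ind[ord, 2L]],
                     stringsAsFactors = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(paste("microbe", "disease", sep = sep),
                        paste(po$microbe, po$disease, sep = sep))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Tabulate prediction scores as a ranked long-format table
#'
#' Flattens a score matrix into a `(disease, microbe, score, rank)` table.
#' With `per_disease_rank = TRUE` ranks restart at 1 within each disease
#' (the prioritisation view used for candidate screening); otherwise a
#' single global ranking is produced. Ties are broken deterministically by
#' ascending (disease name, microbe name).
#'
#' @param scores an `mda_scores` matrix (see [predict_associations()]) or
#'   any named numeric matrix.
#' @param per_disease_rank rank within each disease (default) or globally.
#' @param known optional `mda_assoc` matrix aligned with `scores`; pairs
#'   with `known == 1` are dropped so only candidate (unverified) pairs are
#'   ranked.
#' @return a data frame with columns `disease`, `microbe`, `score`, `rank`.
#' @export
score_table <- function(scores, per_disease_rank = TRUE, known = NULL) {
  if (!is.matrix(scores)) stop("scores must be a matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores must carry microbe row names and disease column names")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  df <- data.frame(
    disease = rep(colnames(scores), each = nrow(scores)),
    microbe = rep(rownames(scores), times = ncol(scores)),
    score = as.vector(scores),
    stringsAsFactors = FALSE
  )
  if (!is.null(known)) {
    if (!identical(dim(known), dim(scores))) {
      stop("known matrix does not match score matrix dimensions")
    }
    df <- df[as.vector(unclass(known)) == 0, , drop = FALSE]
    if (nrow(df) == 0L) stop("no candidate pairs left after excluding known associations")
  }
  if (per_disease_rank) {
    ord <- order(df$disease, -df$score, df$microbe, method = "radix")
    df <- df[ord, , drop = FALSE]
    df$rank <- as.integer(stats::ave(df$score, df$disease,
                                     FUN = seq_along))
  } else {
    ord <- order(-df$score, df$disease, df$microbe, method = "radix")
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
  }
  rownames(df) <- NULL
  df
}

#' Write a ranked score table to a TSV file
#'
#' Serialises [score_table()] output as a 4-column UTF-8 TSV with `\n` line
#' endings. The file is written atomically (temporary file then rename), so
#' a failure leaves no partial output behind.
#'
#' @inheritParams score_table
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, per_disease_rank = TRUE,
                              known = NULL) {
  df <- score_table(scores, per_disease_rank = per_disease_rank, known = known)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(pattern = ".scoretable", tmpdir = dir)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  if (!file.rename(tmp, path)) stop("cannot write output file: ", path)
  ok <- TRUE
  invisible(path)
}
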