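#' Train word embeddings on a tokenized corpus
#'
#' Learns one fixed-length vector per vocabulary token from windowed
#' word-context co-occurrence statistics: counts within a symmetric window
#' are turned into a positive pointwise mutual information (PPMI) matrix,
#' which is factorized by truncated SVD; the embedding is `U * sqrt(S)`.
#' This count-based factorization is the classical equivalent of skip-gram
#' training and shares its two contract parameters — vector dimensionality
#' and context window size — while being exactly reproducible (SVD signs
#' are fixed deterministically, so the same corpus always yields the same
#' table, independent of `seed`).
#'
#' Tokens seen fewer than `min_count` times in total are excluded from the
#' vocabulary.
#'
#' @param tokcorpus a `tokenized_corpus` from [preprocess_corpus()].
#' @param dim vector dimensionality (default 300). If the vocabulary rank
#'   is smaller, trailing components are zero.
#' @param window symmetric context window size in tokens (default 5).
#' @param min_count minimum total token count for vocabulary entry
#'   (default 5).
#' @param seed recorded in the table for provenance; training itself is
#'   deterministic.
#' @return an `embedding_table`: list with `vectors` (numeric matrix,
#'   rownames = terms, `dim` columns), `dim`, `window`, `seed`,
#'   `trained_on` (corpus fingerprint).
#' @export
train_embeddings <- function(tokcorpus, dim = 300, window = 5,
                             min_count = 5, seed = 0) {
  if (length(tokcorpus$tokens) == 0) stop("empty corpus")
  if (dim < 2) stop("embedding dimension must be >= 2")
  cnt <- table(unlist(tokcorpus$tokens))
  vocab <- sort(names(cnt)[cnt >= min_count])
  if (length(vocab) < 2)
    stop("vocabulary has fewer than 2 tokens at min_count = ", min_count)
  V <- length(vocab)

  # accumulate symmetric windowed co-occurrence counts as triplets
  ii <- integer(0); jj <- integer(0)
  acc_i <- vector("list", length(tokcorpus$tokens))
  acc_j <- vector("list", length(tokcorpus$tokens))
  for (d in seq_along(tokcorpus$tokens)) {
    idx <- match(tokcorpus$tokens[[d]], vocab)
    idx <- idx[!is.na(idx)]
    n <- length(idx)
    if (n < 2) next
    di <- integer(0); dj <- integer(0)
    for (k in seq_len(min(window, n - 1))) {
      a <- idx[seq_len(n - k)]
      b <- idx[seq_len(n - k) + k]
      di <- c(di, a, b)
      dj <- c(dj, b, a)
    }
    acc_i[[d]] <- di
    acc_j[[d]] <- dj
  }
  ii <- unlist(acc_i); jj <- unlist(acc_j)
  if (length(ii) == 0) stop("no co-occurrence pairs inside the window")
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(V, V))
  C <- as.matrix(C)

  total <- sum(C)
  pr <- rowSums(C) / total
  pc <- colSums(C) / total
  P <- C / total
  # PPMI: max(0, log p(i,j) - log p(i) - log p(j)); zero cells stay zero
  M <- matrix(0, V, V)
  nz <- P > 0
  M[nz] <- log(P[nz]) - log(outer(pr, pc))[nz]
  M[M < 0] <- 0

  k <- min(dim, V)
  sv <- svd(M, nu = k, nv = 0)
  emb <- sv$u %*% diag(sqrt(sv$d[seq_len(k)]), k)
  # fix signs: the largest-magnitude loading of each component is positive
  for (c in seq_len(k)) {
    j <- which.max(abs(emb[, c]))
    if (emb[j, c] < 0) emb[, c] <- -emb[, c]
  }
  if (k < dim) emb <- cbind(emb, matrix(0, V, dim - k))
  rownames(emb) <- vocab
  emb[!is.finite(emb)] <- 0

  structure(list(
    vectors = emb, dim = as.integer(dim), window = as.integer(window),
    seed = as.integer(seed),
    trained_on = sprintf("docs=%d;tokens=%d;vocab=%d",
                         length(tokcorpus$tokens),
                         length(unlist(tokcorpus$tokens)), V)
  ), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$vectors), " terms x ", x$dim,
      " dims (window ", x$window, ")\n", sep = "")
  invisible(x)
}

#' Construct an embedding table from a ready-made matrix
#' @param m numeric matrix with term rownames.
#' @param window,seed provenance fields.
#' @return an `embedding_table`.
#' @export
embedding_table <- function(m, window = 5, seed = 0) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), all(is.finite(m)))
  structure(list(vectors = m, dim = ncol(m), window = as.integer(window),
                 seed = as.integer(seed), trained_on = "external"),
            class = "embedding_table")
}

#' Cosine similarity of two vectors
#'
#' `cos(x, y) = x . y / (|x| |y|)`, in `[-1, 1]`.
#'
#' @param x,y numeric vectors of equal length, both with positive norm.
#' @return numeric scalar.
#' @export
cosine <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  sum(x * y) / (nx * ny)
}

#' Pairwise cosine distance matrix (1 - cosine) for a set of terms
#' @param emb an `embedding_table`.
#' @param terms character vector; all must be embedded.
#' @return a symmetric distance matrix.
#' @keywords internal
cosine_dist <- function(emb, terms) {
  missing <- setdiff(terms, rownames(emb$vectors))
  if (length(missing) > 0)
    stop("term(s) without embedding: ", paste(missing, collapse = ", "))
  X <- emb$vectors[terms, , drop = FALSE]
  nr <- sqrt(rowSums(X^2))
  if (any(nr == 0)) stop("zero-norm embedding among the requested terms")
  S <- (X / nr) %*% t(X / nr)
  D <- 1 - S
  D[D < 0] <- 0     # numerical guard
  diag(D) <- 0
  D
}

#' Project embeddings to 2-D for plotting
#'
#' Deterministic principal-component projection of the selected term
#' vectors (centered, unscaled; component signs fixed by the
#' largest-magnitude loading). Used for visual inspection of embedding
#' quality only.
#'
#' @param emb an `embedding_table`.
#' @param terms at least 3 embedded terms.
#' @param seed accepted for interface stability; the projection is
#'   deterministic and ignores it.
#' @return numeric matrix `length(terms) x 2`, rownames = terms.
#' @export
project_2d <- function(emb, terms, seed = 0) {
  missing <- setdiff(terms, rownames(emb$vectors))
  if (length(missing) > 0)
    stop("term(s) without embedding: ", paste(missing, collapse = ", "))
  if (length(terms) < 3) stop("need at least 3 terms to project")
  X <- emb$vectors[terms, , drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 2, nv = 2)
  Y <- sv$u %*% diag(sv$d[1:2], 2)
  for (c in 1:2) {
    j <- which.max(abs(Y[, c]))
    if (length(j) && Y[j, c] < 0) Y[, c] <- -Y[, c]
  }
  rownames(Y) <- terms
  colnames(Y) <- c("x", "y")
  Y
}

#' Write an embedding table in word2vec text format
#'
#' Header line `"<n> <dim>"`, then one line per term: the token followed by
#' its components, space-separated.
#'
#' @param emb an `embedding_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(emb, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb$vectors), emb$dim), con)
  for (k in seq_len(nrow(emb$vectors))) {
    writeLines(paste(rownames(emb$vectors)[k],
                     paste(format(emb$vectors[k, ], digits = 17,
                                  scientific = TRUE, trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Read a word2vec text-format vector file
#' @param path path to a word2vec text file.
#' @return an `embedding_table`.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "[ ]+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop("malformed word2vec header in ", path)
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) < n + 1) stop("truncated word2vec file: ", path)
  m <- matrix(NA_real_, n, d)
  terms <- character(n)
  for (k in seq_len(n)) {
    parts <- strsplit(trimws(lines[k + 1]), "[ ]+")[[1]]
    terms[k] <- parts[1]
    m[k, ] <- as.numeric(parts[-1])
  }
  rownames(m) <- terms
  embedding_table(m)
}
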