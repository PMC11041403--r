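# Independent oracles used across the suite. Each is a deliberately naive
# second implementation, kept free of the package's own code paths.

# brute-force document-membership co-occurrence tensor
oracle_tensor <- function(tokens_list, yms, ai_order, bio_order, binning) {
  counts <- array(0L, c(binning$n_bins, length(ai_order), length(bio_order)),
                  dimnames = list(binning$labels, ai_order, bio_order))
  for (d in seq_along(tokens_list)) {
    t <- (yms[d] - binning$start) %/% binning$bin_months + 1L
    for (i in seq_along(ai_order)) {
      if (!ai_order[i] %in% tokens_list[[d]]) next
      for (j in seq_along(bio_order)) {
        if (bio_order[j] %in% tokens_list[[d]])
          counts[t, i, j] <- counts[t, i, j] + 1L
      }
    }
  }
  counts
}

# naive O(n^3) agglomerative clustering with Lance-Williams updates,
# reproducing hclust's merge numbering and leaf-order conventions:
# within a merge row singletons (ascending index) precede clusters
# (ascending step), and the leaf order expands each row left-then-right.
naive_agglom <- function(D, method = c("average", "complete")) {
  method <- match.arg(method)
  n <- nrow(D)
  D <- as.matrix(D)
  diag(D) <- Inf
  active <- seq_len(n)          # current cluster ids: -i leaf, +step cluster
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- which(D == min(D), arr.ind = TRUE)[1, ]
    a <- min(m); b <- max(m)
    pair <- sort_pair(ids[a], ids[b])
    merge[s, ] <- pair
    height[s] <- D[a, b]
    # Lance-Williams update into slot a
    for (k in seq_len(n)) {
      if (k == a || k == b || sizes[k] == 0L) next
      D[a, k] <- D[k, a] <- switch(method,
        average = (sizes[a] * D[k, a] + sizes[b] * D[k, b]) /
          (sizes[a] + sizes[b]),
        complete = max(D[k, a], D[k, b])
      )
    }
    sizes[a] <- sizes[a] + sizes[b]
    ids[a] <- s
    D[b, ] <- Inf; D[, b] <- Inf
    sizes[b] <- 0L
  }
  list(merge = merge, height = height,
       order = expand_leaves(merge, n - 1L))
}

sort_pair <- function(x, y) {
  # singletons (negative) first, each group ascending by index/step
  v <- c(x, y)
  neg <- sort(-v[v < 0])
  pos <- sort(v[v > 0])
  c(-neg, pos)
}

expand_leaves <- function(merge, row) {
  out <- integer(0)
  for (e in merge[row, ]) {
    out <- c(out, if (e < 0) -e else expand_leaves(merge, e))
  }
  out
}

# plain cyclic coordinate descent for the elastic net
#   1/(2n) ||y - b0 - X b||^2 + lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
# on already-standardized X (column means 0)
cd_enet <- function(X, y, lambda, alpha, iters = 5000, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  b <- rep(0, p)
  b0 <- mean(y)
  xx <- colSums(X^2) / n
  r <- y - b0
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xx[j] == 0) next
      rho <- sum(X[, j] * r) / n + xx[j] * b[j]
      bj <- sign(rho) * max(0, abs(rho) - lambda * alpha) /
        (xx[j] + lambda * (1 - alpha))
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol) break
  }
  list(coef = b, intercept = b0)
}

# mean silhouette of a 2-cluster labelling on 2-D points
silhouette2 <- function(Y, labels) {
  D <- as.matrix(dist(Y))
  s <- vapply(seq_len(nrow(Y)), function(k) {
    own <- labels == labels[k]
    own[k] <- FALSE
    a <- if (any(own)) mean(D[k, own]) else 0
    b <- mean(D[k, !labels %in% labels[k]])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# write a corpus data.frame (doc_id, ym, title, abstract) as a tabular file
write_tabular_corpus <- function(records, path) {
  df <- data.frame(
    doc_id = records$doc_id,
    date = sprintf("%04d-%02d", records$ym %/% 12, records$ym %% 12 + 1),
    title = records$title,
    abstract = records$abstract,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# two-record MEDLINE-style XML fixture, written on demand
write_medline_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<PubmedArticleSet>",
    "  <PubmedArticle>",
    "    <MedlineCitation>",
    "      <PMID>10000001</PMID>",
    "      <Article>",
    "        <ArticleTitle>Machine learning triage of CT scans</ArticleTitle>",
    "        <Abstract>",
    "          <AbstractText>Machine learning improves CT-based triage in 2021.</AbstractText>",
    "        </Abstract>",
    "        <Journal><JournalIssue><PubDate>",
    "          <Year>2021</Year><Month>Mar</Month>",
    "        </PubDate></JournalIssue></Journal>",
    "      </Article>",
    "    </MedlineCitation>",
    "  </PubmedArticle>",
    "  <PubmedArticle>",
    "    <MedlineCitation>",
    "      <PMID>10000002</PMID>",
    "      <Article>",
    "        <ArticleTitle>Neural networks for tumor detection</ArticleTitle>",
    "        <Abstract>",
    "          <AbstractText Label=\"BACKGROUND\">Neural networks detect tumors.</AbstractText>",
    "          <AbstractText Label=\"RESULTS\">Accuracy was high.</AbstractText>",
    "        </Abstract>",
    "        <Journal><JournalIssue><PubDate>",
    "          <Year>2019</Year>",
    "        </PubDate></JournalIssue></Journal>",
    "      </Article>",
    "    </MedlineCitation>",
    "  </PubmedArticle>",
    "</PubmedArticleSet>"
  ), path)
  path
}
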