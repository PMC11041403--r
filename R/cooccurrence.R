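#' Time binning of a corpus span
#'
#' Tiles the inclusive span `[start, end]` with consecutive bins of
#' `bin_months` months. The span length must be an exact multiple of the
#' bin length, so every date maps to exactly one bin. With the defaults
#' (January 2000 to December 2021, 6-month bins) this yields 44 semiannual
#' bins, January-June and July-December of each year.
#'
#' @param start,end span bounds, `"YYYY-MM"` strings or ym integers.
#' @param bin_months bin length in months (default 6).
#' @return a `time_binning`: list with `start`, `end` (ym integers),
#'   `bin_months`, `n_bins`, `labels`.
#' @export
time_binning <- function(start = "2000-01", end = "2021-12", bin_months = 6) {
  s <- if (is.character(start)) parse_ym(start) else as.integer(start)
  e <- if (is.character(end)) parse_ym(end) else as.integer(end)
  if (is.na(s) || is.na(e)) stop("unparseable binning bound")
  if (s > e) stop("inverted binning span")
  months <- e - s + 1L
  if (months %% bin_months != 0)
    stop("span of ", months, " months is not a multiple of bin length ",
         bin_months)
  n <- months %/% bin_months
  starts <- s + (seq_len(n) - 1L) * bin_months
  labels <- vapply(starts, function(b) {
    if (bin_months == 6)
      sprintf("%04dH%d", ym_year(b), if (ym_month(b) <= 6) 1L else 2L)
    else format_ym(b)
  }, character(1))
  structure(list(start = s, end = e, bin_months = as.integer(bin_months),
                 n_bins = n, labels = labels),
            class = "time_binning")
}

#' Map year-month dates to bin indices
#' @param binning a `time_binning`.
#' @param ymv integer ym vector.
#' @return integer bin indices in `1..n_bins`; error if out of span.
#' @export
bin_index <- function(binning, ymv) {
  if (any(ymv < binning$start | ymv > binning$end))
    stop("date(s) outside the binning span; filter_span() first")
  (ymv - binning$start) %/% binning$bin_months + 1L
}

#' Order terms by agglomerative clustering of their embeddings
#'
#' Hierarchically clusters the term vectors bottom-up on cosine distance
#' (`1 - cosine`) and returns the dendrogram leaf order, which places
#' semantically similar terms at adjacent rows/columns of the
#' co-occurrence matrix. Terms with identical vectors merge at height 0
#' and are therefore adjacent.
#'
#' @param emb an `embedding_table`.
#' @param terms at least 2 embedded terms.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (Ward's criterion on cosine distance, `hclust`'s `"ward.D2"`).
#' @return a `cluster_order`: list with `order` (terms in leaf order) and
#'   `hclust` (the merge tree).
#' @export
cluster_order <- function(emb, terms, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (length(terms) < 2) stop("need at least 2 terms to cluster")
  D <- cosine_dist(emb, terms)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(D), method = method)
  structure(list(order = terms[hc$order], hclust = hc, linkage = linkage),
            class = "cluster_order")
}

#' Build the time-binned co-occurrence tensor
#'
#' `counts[t, i, j]` is the number of documents in bin `t` whose token set
#' contains both `ai_order[i]` and `bio_order[j]`; repeated mentions within
#' one abstract count once. Axis orderings are normally dendrogram leaf
#' orders from [cluster_order()] so that the spatial window of a cell spans
#' semantically similar keyword pairs.
#'
#' @param tokcorpus a `tokenized_corpus`; every document date must fall
#'   inside the binning span.
#' @param ai_order,bio_order keyword axis orderings (character vectors),
#'   or `cluster_order` objects.
#' @param binning a `time_binning`.
#' @return a `cooc_tensor`: list with `counts` (integer array
#'   `n_bins x k_ai x k_bio` with dimnames), `binning`, `ai_order`,
#'   `bio_order`.
#' @export
count_tensor <- function(tokcorpus, ai_order, bio_order, binning) {
  if (inherits(ai_order, "cluster_order")) ai_order <- ai_order$order
  if (inherits(bio_order, "cluster_order")) bio_order <- bio_order$order
  stopifnot(length(ai_order) >= 1, length(bio_order) >= 1,
            !anyDuplicated(ai_order), !anyDuplicated(bio_order))
  tb <- bin_index(binning, tokcorpus$ym)
  counts <- array(0L, dim = c(binning$n_bins, length(ai_order), length(bio_order)),
                  dimnames = list(binning$labels, ai_order, bio_order))
  for (d in seq_along(tokcorpus$tokens)) {
    u <- unique(tokcorpus$tokens[[d]])
    a <- which(ai_order %in% u)
    if (length(a) == 0) next
    b <- which(bio_order %in% u)
    if (length(b) == 0) next
    t <- tb[d]
    counts[t, a, b] <- counts[t, a, b] + 1L
  }
  new_cooc_tensor(counts, binning, ai_order, bio_order)
}

new_cooc_tensor <- function(counts, binning, ai_order, bio_order) {
  structure(list(counts = counts, binning = binning,
                 ai_order = ai_order, bio_order = bio_order),
            class = "cooc_tensor")
}

#' @export
print.cooc_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat("<cooc_tensor> ", d[1], " bins x ", d[2], " AI terms x ", d[3],
      " biomedical terms; total count ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' One bin of a tensor as a count matrix
#' @param tensor a `cooc_tensor`.
#' @param t bin index.
#' @return integer matrix `k_ai x k_bio`.
#' @export
tensor_slice <- function(tensor, t) {
  d <- dim(tensor$counts)
  stopifnot(t >= 1, t <= d[1])
  matrix(tensor$counts[t, , ], d[2], d[3],
         dimnames = list(tensor$ai_order, tensor$bio_order))
}

#' Log-scale heat transform
#'
#' Elementwise `log10(1 + count)`: zero cells map to zero heat, a count of
#' 9 to 1, 99 to 2, and so on.
#'
#' @param m nonnegative count matrix (or array).
#' @return numeric matrix of the same shape.
#' @export
log_heat <- function(m) {
  if (any(m < 0)) stop("log heat expects nonnegative counts")
  log10(1 + m)
}

#' Write a tensor as per-bin TSV matrices plus a JSON sidecar
#'
#' Each bin becomes `<stem>_<label>.tsv` (rows = AI keywords in order,
#' columns = biomedical keywords in order); `<stem>.json` records the
#' binning and the axis orderings.
#'
#' @param tensor a `cooc_tensor`.
#' @param stem output path stem (no extension).
#' @return character vector of written paths, invisibly.
#' @export
write_tensor <- function(tensor, stem) {
  paths <- character(0)
  for (t in seq_len(dim(tensor$counts)[1])) {
    p <- sprintf("%s_%s.tsv", stem, tensor$binning$labels[t])
    m <- tensor_slice(tensor, t)
    utils::write.table(m, p, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    paths <- c(paths, p)
  }
  side <- sprintf("%s.json", stem)
  jsonlite::write_json(list(
    start = format_ym(tensor$binning$start),
    end = format_ym(tensor$binning$end),
    bin_months = tensor$binning$bin_months,
    labels = tensor$binning$labels,
    ai_order = tensor$ai_order, bio_order = tensor$bio_order
  ), side, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, side))
}

#' Read a tensor written by [write_tensor()]
#' @param stem path stem used at write time.
#' @return a `cooc_tensor`.
#' @export
read_tensor <- function(stem) {
  meta <- jsonlite::fromJSON(sprintf("%s.json", stem))
  binning <- time_binning(meta$start, meta$end, meta$bin_months)
  counts <- array(0L, c(binning$n_bins, length(meta$ai_order),
                        length(meta$bio_order)),
                  dimnames = list(binning$labels, meta$ai_order, meta$bio_order))
  for (t in seq_len(binning$n_bins)) {
    p <- sprintf("%s_%s.tsv", stem, binning$labels[t])
    m <- as.matrix(utils::read.delim(p, row.names = 1, check.names = FALSE))
    counts[t, , ] <- as.integer(m)
  }
  new_cooc_tensor(counts, binning, meta$ai_order, meta$bio_order)
}
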