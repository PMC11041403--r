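#' Ranked proportion-of-publications table
#'
#' For every (AI, biomedical) keyword pair, the share of corpus documents
#' in the period whose abstract mentions both terms:
#' `100 * sum_t counts[t,i,j] / sum_t total_docs[t]` over the selected
#' bins. Pairs with zero count are not ranked.
#'
#' @param tensor a `cooc_tensor` (observed counts) or a numeric array of
#'   the same layout (e.g. predicted matrices stacked over bins).
#' @param bins integer vector of bin indices to aggregate.
#' @param total_docs per-bin document totals, either a full-length vector
#'   (one entry per tensor bin) or one entry per selected bin.
#' @param top_n number of rows to keep (default 20).
#' @return a `trend_table`: `data.frame` with `rank`, `ai_term`,
#'   `bio_term`, `value` (percent), `count`, sorted by value descending
#'   (ties broken lexicographically); attributes `metric = "proportion"`,
#'   `bins`, `total_docs`.
#' @export
proportion_table <- function(tensor, bins, total_docs, top_n = 20) {
  counts <- tensor_counts(tensor)
  nb <- dim(counts)[1]
  stopifnot(all(bins >= 1), all(bins <= nb))
  if (length(total_docs) == nb) total_docs <- total_docs[bins]
  stopifnot(length(total_docs) == length(bins))
  denom <- sum(total_docs)
  if (denom <= 0) stop("zero total documents in the period")
  agg <- apply(counts[bins, , , drop = FALSE], c(2, 3), sum)
  df <- pair_frame(tensor, agg)
  df <- df[df$count > 0, , drop = FALSE]
  df$value <- 100 * df$count / denom
  rank_table(df, top_n, metric = "proportion",
             meta = list(bins = bins, total_docs = sum(total_docs)))
}

#' Ranked percentage-growth table with threshold filtering
#'
#' Growth of a pair between two disjoint, ordered periods:
#' `100 * (recent - past) / past`, computed only for pairs whose past
#' count reaches the threshold — tiny bases otherwise produce huge,
#' meaningless percentages (the reason a filter threshold exists).
#'
#' @param tensor a `cooc_tensor` or compatible numeric array.
#' @param past_bins,recent_bins disjoint bin-index ranges, past before
#'   recent. Defaults correspond to "last 5 years vs the 5 years before"
#'   only when set by the caller; there is no implicit default period.
#' @param threshold minimum past-period count (default 10).
#' @param top_n rows to keep (default 20).
#' @return a `trend_table` with `rank`, `ai_term`, `bio_term`, `value`
#'   (percent growth), `past_count`, `recent_count`; attribute
#'   `metric = "growth"`, plus `threshold` and the two bin ranges.
#' @export
growth_table <- function(tensor, past_bins, recent_bins, threshold = 10,
                         top_n = 20) {
  counts <- tensor_counts(tensor)
  nb <- dim(counts)[1]
  if (length(past_bins) == 0 || length(recent_bins) == 0)
    stop("empty bin range")
  stopifnot(all(c(past_bins, recent_bins) >= 1),
            all(c(past_bins, recent_bins) <= nb), threshold >= 1)
  if (length(intersect(past_bins, recent_bins)) > 0)
    stop("past and recent bin ranges overlap")
  if (max(past_bins) >= min(recent_bins))
    stop("past bins must precede recent bins")
  past <- apply(counts[past_bins, , , drop = FALSE], c(2, 3), sum)
  recent <- apply(counts[recent_bins, , , drop = FALSE], c(2, 3), sum)
  df <- pair_frame(tensor, past)
  names(df)[names(df) == "count"] <- "past_count"
  df$recent_count <- as.vector(recent)
  df <- df[df$past_count >= threshold, , drop = FALSE]
  df$value <- 100 * (df$recent_count - df$past_count) / df$past_count
  rank_table(df, top_n, metric = "growth",
             meta = list(past_bins = past_bins, recent_bins = recent_bins,
                         threshold = threshold))
}

# counts array from either a cooc_tensor or a bare array
tensor_counts <- function(tensor) {
  if (inherits(tensor, "cooc_tensor")) tensor$counts else {
    stopifnot(length(dim(tensor)) == 3)
    tensor
  }
}

pair_frame <- function(tensor, agg) {
  ai <- if (inherits(tensor, "cooc_tensor")) tensor$ai_order else
    rownames(agg) %||% paste0("ai", seq_len(nrow(agg)))
  bio <- if (inherits(tensor, "cooc_tensor")) tensor$bio_order else
    colnames(agg) %||% paste0("bio", seq_len(ncol(agg)))
  data.frame(
    ai_term = rep(ai, times = length(bio)),
    bio_term = rep(bio, each = length(ai)),
    count = as.vector(agg),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rank_table <- function(df, top_n, metric, meta) {
  df <- df[order(-df$value, df$ai_term, df$bio_term), , drop = FALSE]
  df <- utils::head(df, top_n)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  first <- c("rank", "ai_term", "bio_term", "value")
  df <- df[c(first, setdiff(names(df), first))]
  out <- structure(df, metric = metric, class = c("trend_table", "data.frame"))
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}

#' @export
print.trend_table <- function(x, ...) {
  cat("<trend_table> metric=", attr(x, "metric"), ", ", nrow(x), " row(s)\n",
      sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Write a trend table as TSV with metadata header comments
#' @param tt a `trend_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trend_table <- function(tt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric=%s", attr(tt, "metric")), con)
  if (!is.null(attr(tt, "threshold")))
    writeLines(sprintf("# threshold=%d", attr(tt, "threshold")), con)
  utils::write.table(as.data.frame(tt), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Difference between predicted and actual matrices
#'
#' Elementwise `pred - actual`, the matrix behind difference heatmaps.
#'
#' @param pred predicted real matrix.
#' @param actual observed count matrix of the same shape.
#' @return numeric matrix.
#' @export
difference_matrix <- function(pred, actual) {
  if (!all(dim(pred) == dim(actual))) stop("shape mismatch")
  pred - actual
}
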