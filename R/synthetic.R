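#' Define a synthetic trend scenario
#'
#' A scenario states a known world for testing: a `k_ai x k_bio` keyword
#' grid observed over `bins` semiannual periods, where each pair's
#' expected co-occurrence count follows a parametric intensity trajectory
#' with optional spatial correlation across the (clustered) keyword axes,
#' and observed counts are Poisson draws around the intensity.
#'
#' Dynamics types (`m_t` multiplies the pair's base intensity, `t` the
#' 1-based bin):
#' * `constant`: `m_t = 1`.
#' * `linear`: `m_t = 1 + slope * (t - 1)` (error if negative anywhere).
#' * `exponential`: `m_t = rate^(t - 1)`.
#' * `changepoint`: `m_t = 1` before `bin`, `factor` from `bin` on.
#'
#' Per-pair base intensities are Gamma-distributed with mean `base_rate`
#' and shape 4 (coefficient of variation 0.5), a realistic heterogeneity
#' for keyword-pair popularity. `spatial_corr` applies one pass of
#' 8-neighbor averaging to each bin's intensity grid with weight `rho`:
#' `lambda <- (1 - rho) * lambda + rho * neighbor_mean(lambda)`, which
#' plants exactly the neighborhood structure the spatial forecasting
#' window is designed to exploit.
#'
#' @param k_ai,k_bio axis sizes.
#' @param bins number of semiannual bins (0 allowed: empty world).
#' @param base_rate mean co-occurrence count per pair per bin.
#' @param dynamics list with `type` and its parameter(s), see above.
#' @param spatial_corr neighborhood smoothing weight in `[0, 1)`.
#' @param seed integer seed; the same scenario always generates identical
#'   output.
#' @param multiword_every every n-th keyword of each axis is a two-word
#'   surface phrase (merged token with `+`), exercising the merge rule;
#'   0 disables.
#' @param background_docs filler-only documents added per bin by
#'   [generate_corpus()] (they carry no keywords).
#' @return a `trend_scenario` list.
#' @export
trend_scenario <- function(k_ai = 10, k_bio = 15, bins = 12, base_rate = 20,
                           dynamics = list(type = "constant"),
                           spatial_corr = 0, seed = 1,
                           multiword_every = 5, background_docs = 10) {
  stopifnot(k_ai >= 1, k_bio >= 1, bins >= 0, base_rate >= 0,
            spatial_corr >= 0, spatial_corr < 1)
  type <- match.arg(dynamics$type,
                    c("constant", "linear", "exponential", "changepoint"))
  if (bins > 0) {
    m <- trajectory_multipliers(dynamics, bins)
    if (any(m < 0)) stop("scenario yields negative intensities")
  }
  structure(list(k_ai = k_ai, k_bio = k_bio, bins = bins,
                 base_rate = base_rate, dynamics = dynamics,
                 spatial_corr = spatial_corr, seed = as.integer(seed),
                 multiword_every = multiword_every,
                 background_docs = background_docs),
            class = "trend_scenario")
}

trajectory_multipliers <- function(dynamics, bins) {
  t <- seq_len(bins)
  switch(dynamics$type,
    constant = rep(1, bins),
    linear = 1 + dynamics$slope * (t - 1),
    exponential = dynamics$rate^(t - 1),
    changepoint = ifelse(t < dynamics$bin, 1, dynamics$factor),
    stop("unknown dynamics type: ", dynamics$type)
  )
}

# one pass of 8-neighbor smoothing; edge cells average their available
# neighbors
smooth_grid <- function(m, rho) {
  if (rho == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc)
  n <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    s[ri - di, rj - dj] <- s[ri - di, rj - dj] + m[ri, rj]
    n[ri - di, rj - dj] <- n[ri - di, rj - dj] + 1
  }
  (1 - rho) * m + rho * s / n
}

# letter-only suffixes: aa, ab, ..., deterministic, regex-safe
term_suffixes <- function(k) {
  stopifnot(k <= 26^3)
  g <- expand.grid(a = letters, b = letters, c = letters,
                   stringsAsFactors = FALSE)
  paste0(g$c, g$b, g$a)[seq_len(k)]
}

# keyword tokens for one axis; every multiword_every-th term is a merged
# two-word phrase (token "base+tail", surface "base tail")
axis_terms <- function(prefix, tail, k, multiword_every) {
  suf <- term_suffixes(k)
  base <- paste0(prefix, suf)
  token <- base
  if (multiword_every > 0) {
    mw <- seq_len(k) %% multiword_every == 0
    token[mw] <- paste0(base[mw], "+", tail)
  }
  token
}

term_surface <- function(token) gsub("+", " ", token, fixed = TRUE)

#' Generate a synthetic co-occurrence tensor with known intensities
#'
#' Draws `counts[t, i, j] ~ Poisson(lambda_t(i, j))` where the intensity
#' array follows the scenario's trajectory and spatial smoothing. The
#' ground-truth intensity array is returned alongside the tensor.
#'
#' @param scenario a `trend_scenario`.
#' @return list with `tensor` (a `cooc_tensor`), `intensity` (numeric
#'   array of the same shape), `ai_order`, `bio_order`.
#' @export
generate_tensor <- function(scenario) {
  s <- scenario
  ai <- axis_terms("aiq", "model", s$k_ai, s$multiword_every)
  bio <- axis_terms("bioq", "disease", s$k_bio, s$multiword_every)
  if (s$bins == 0) {
    counts <- array(0L, c(0, s$k_ai, s$k_bio),
                    dimnames = list(NULL, ai, bio))
    tensor <- new_cooc_tensor(counts, NULL, ai, bio)
    return(list(tensor = tensor,
                intensity = array(0, c(0, s$k_ai, s$k_bio)),
                ai_order = ai, bio_order = bio))
  }
  binning <- time_binning(ym(2000L, 1L),
                          ym(2000L, 1L) + s$bins * 6L - 1L, 6)
  set.seed(s$seed)
  base <- matrix(if (s$base_rate > 0)
    stats::rgamma(s$k_ai * s$k_bio, shape = 4, rate = 4 / s$base_rate)
    else 0, s$k_ai, s$k_bio)
  mult <- trajectory_multipliers(s$dynamics, s$bins)
  intensity <- array(0, c(s$bins, s$k_ai, s$k_bio))
  counts <- array(0L, c(s$bins, s$k_ai, s$k_bio),
                  dimnames = list(binning$labels, ai, bio))
  for (t in seq_len(s$bins)) {
    lam <- smooth_grid(base * mult[t], s$spatial_corr)
    intensity[t, , ] <- lam
    counts[t, , ] <- stats::rpois(length(lam), as.vector(lam))
  }
  list(tensor = new_cooc_tensor(counts, binning, ai, bio),
       intensity = intensity, ai_order = ai, bio_order = bio)
}

# deliberately ordinary filler vocabulary; never collides with the
# prefixed keyword tokens
filler_words <- c(
  "the", "of", "and", "in", "with", "for", "patients", "study", "results",
  "analysis", "using", "based", "clinical", "data", "method", "approach",
  "showed", "significant", "performance", "evaluation", "compared",
  "proposed", "novel", "system", "accuracy", "between", "during", "after",
  "treatment", "diagnosis", "cohort", "across", "observed", "framework",
  "applied", "improved", "findings", "measured", "samples", "outcomes"
)

#' Generate a synthetic corpus realizing a planted tensor
#'
#' Emits one dated abstract per planted co-occurrence: a document for cell
#' `(t, i, j)` contains exactly one AI keyword and one biomedical keyword
#' (multiword keywords in their unmerged surface form, to exercise the
#' merge rule) embedded in filler text with digits and punctuation, plus
#' `background_docs` filler-only documents per bin. Document-level
#' counting of the planted keywords therefore reproduces the generated
#' tensor exactly.
#'
#' @param scenario a `trend_scenario`.
#' @return list with `records` (corpus `data.frame` as from
#'   [read_corpus()]), `tensor` (the planted `cooc_tensor`), `intensity`,
#'   `ai_order`, `bio_order`, `merge_phrases` (surface phrases to pass to
#'   [preprocess_corpus()]), `total_docs` (per-bin document totals),
#'   `binning`.
#' @export
generate_corpus <- function(scenario) {
  gt <- generate_tensor(scenario)
  s <- scenario
  counts <- gt$tensor$counts
  merge_phrases <- term_surface(grep("+", c(gt$ai_order, gt$bio_order),
                                     fixed = TRUE, value = TRUE))
  if (s$bins == 0) {
    rec <- data.frame(doc_id = character(0), ym = integer(0),
                      title = character(0), abstract = character(0),
                      stringsAsFactors = FALSE)
    return(c(gt, list(records = rec, merge_phrases = merge_phrases,
                      total_docs = integer(0), binning = NULL)))
  }
  binning <- gt$tensor$binning
  # RNG continues from the tensor-generation stream: still fully
  # deterministic under the scenario seed
  n_pair_docs <- sum(counts)
  n_total <- n_pair_docs + s$bins * s$background_docs
  ids <- character(n_total); yms <- integer(n_total)
  abstracts <- character(n_total); k <- 0L
  make_abstract <- function(surfaces) {
    n_fill <- sample(8:15, 1)
    words <- sample(filler_words, n_fill, replace = TRUE)
    # sprinkle the noise preprocessing must remove
    words[1] <- paste0(words[1], ",")
    words <- c(words, sprintf("(%d)", sample(1900:2030, 1)))
    for (sf in surfaces) {
      pos <- sample(seq_len(length(words) + 1), 1)
      words <- append(words, sf, after = pos - 1)
    }
    paste(words, collapse = " ")
  }
  for (t in seq_len(s$bins)) {
    bin_start <- binning$start + (t - 1L) * binning$bin_months
    for (i in seq_len(s$k_ai)) for (j in seq_len(s$k_bio)) {
      c_ij <- counts[t, i, j]
      if (c_ij == 0) next
      for (r in seq_len(c_ij)) {
        k <- k + 1L
        ids[k] <- sprintf("S%07d", k)
        yms[k] <- bin_start + (k %% binning$bin_months)
        abstracts[k] <- make_abstract(term_surface(
          c(gt$ai_order[i], gt$bio_order[j])))
      }
    }
    for (r in seq_len(s$background_docs)) {
      k <- k + 1L
      ids[k] <- sprintf("S%07d", k)
      yms[k] <- bin_start + (k %% binning$bin_months)
      abstracts[k] <- make_abstract(character(0))
    }
  }
  rec <- data.frame(doc_id = ids, ym = yms, title = "",
                    abstract = abstracts, stringsAsFactors = FALSE)
  total_docs <- as.integer(table(factor(bin_index(binning, rec$ym),
                                        levels = seq_len(s$bins))))
  c(gt, list(records = rec, merge_phrases = merge_phrases,
             total_docs = total_docs, binning = binning))
}

#' Generate a clustered Gaussian embedding fixture
#'
#' `n_clusters` isotropic Gaussian clusters (unit within-cluster standard
#' deviation) whose centers sit at norm `separation` in random directions,
#' so between-center distances scale with `separation` relative to the
#' within-cluster spread. Supports domain-classification and
#' clustering-order tests with known labels.
#'
#' @param n_clusters number of clusters.
#' @param terms_per_cluster terms in each cluster.
#' @param dim embedding dimensionality (default 10).
#' @param separation center norm relative to unit within-cluster sd
#'   (must be positive).
#' @param seed integer seed.
#' @return list with `emb` (an `embedding_table`) and `labels` (integer
#'   cluster id per term, named).
#' @export
generate_embedding_fixture <- function(n_clusters, terms_per_cluster,
                                       dim = 10, separation = 5, seed = 1) {
  stopifnot(separation > 0, n_clusters >= 1, terms_per_cluster >= 1)
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_clusters * dim), n_clusters, dim)
  centers <- centers / sqrt(rowSums(centers^2)) * separation
  n <- n_clusters * terms_per_cluster
  labels <- rep(seq_len(n_clusters), each = terms_per_cluster)
  X <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * dim), n, dim)
  csuf <- term_suffixes(n_clusters)
  tsuf <- term_suffixes(terms_per_cluster)
  terms <- paste0("term", csuf[labels], tsuf[rep(seq_len(terms_per_cluster),
                                                 times = n_clusters)])
  rownames(X) <- terms
  names(labels) <- terms
  list(emb = embedding_table(X, seed = seed), labels = labels)
}
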