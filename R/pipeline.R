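#' Assemble a pipeline run configuration
#'
#' Validates and fills defaults for the end-to-end driver. `corpus` is a
#' path (with `corpus_format`) to a dated-abstract file; `ai_lexicon` /
#' `bio_lexicon` are one-phrase-per-line reference files.
#'
#' @param corpus corpus file path.
#' @param corpus_format `"tabular"`, `"jsonl"` or `"medline-xml"`.
#' @param ai_lexicon,bio_lexicon lexicon file paths.
#' @param out_dir output directory (created if missing).
#' @param k_ai,k_bio keyword budgets.
#' @param span_start,span_end corpus span (`"YYYY-MM"`).
#' @param bin_months time-bin length.
#' @param dim,window embedding dimensionality and context window.
#' @param min_count embedding vocabulary threshold.
#' @param merge_list optional path to a merge-phrase file (one phrase per
#'   line), or a character vector of phrases.
#' @param window_sizes odd forecast window sizes to sweep.
#' @param backends forecast backend names.
#' @param forecast_start,forecast_horizon recurrent forecast anchor bin
#'   (1-based) and number of bins; `NULL` start means the last observed
#'   bin.
#' @param threshold growth-table base-count threshold.
#' @param top_n trend-table length.
#' @param linkage clustering linkage.
#' @param seed integer seed for every stochastic stage.
#' @return a validated `run_config` list.
#' @export
run_config <- function(corpus, corpus_format = "tabular",
                       ai_lexicon, bio_lexicon, out_dir,
                       k_ai = 500, k_bio = 1000,
                       span_start = "2000-01", span_end = "2021-12",
                       bin_months = 6, dim = 300, window = 5,
                       min_count = 5, merge_list = character(),
                       window_sizes = c(1, 3), backends = "ridge",
                       forecast_start = NULL, forecast_horizon = 4,
                       threshold = 10, top_n = 20,
                       linkage = "average", seed = 0) {
  bad <- setdiff(backends, forecast_backends)
  if (length(bad) > 0)
    stop("unknown backend(s) in config: ", paste(bad, collapse = ", "))
  if (any(window_sizes %% 2 != 1)) stop("window sizes must be odd")
  cfg <- list(corpus = corpus, corpus_format = corpus_format,
              ai_lexicon = ai_lexicon, bio_lexicon = bio_lexicon,
              out_dir = out_dir, k_ai = k_ai, k_bio = k_bio,
              span_start = span_start, span_end = span_end,
              bin_months = bin_months, dim = dim, window = window,
              min_count = min_count, merge_list = merge_list,
              window_sizes = window_sizes, backends = backends,
              forecast_start = forecast_start,
              forecast_horizon = forecast_horizon,
              threshold = threshold, top_n = top_n,
              linkage = linkage, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

# tiny FNV-1a content hash for provenance (no external digest dependency)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (h may exceed the integer range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))
}

#' Run the full pipeline: ingest, embed, vocab, tensor, forecast, trends
#'
#' Executes all six stages against a corpus file, writing every stage's
#' artifact plus a provenance manifest (`manifest.json`: config, config
#' hash, seed, package version, per-stage outputs, skip counters) into
#' `out_dir`. The embedding stage precedes keyword selection because the
#' domain classifier needs vectors. A stage failure aborts the run with
#' the stage name in the error.
#'
#' @param config a `run_config`.
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("cowordcast")),
                   r_version = as.character(getRversion()),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(...) file.path(config$out_dir, ...)

  # --- ingest ---------------------------------------------------------
  merge_phrases <- if (is.character(config$merge_list) &&
                       length(config$merge_list) == 1 &&
                       file.exists(config$merge_list))
    read_lexicon(config$merge_list) else config$merge_list
  ing <- stage("ingest", {
    corpus <- read_corpus(config$corpus, config$corpus_format)
    skipped <- attr(corpus, "skipped")
    corpus <- filter_span(corpus, config$span_start, config$span_end)
    write_corpus_jsonl(corpus, out("corpus.jsonl"))
    list(corpus = corpus, skipped = skipped)
  })
  tok <- preprocess_corpus(ing$corpus, merge_phrases)
  manifest$stages$ingest <- list(output = "corpus.jsonl",
                                 n_docs = nrow(ing$corpus),
                                 skipped = ing$skipped)

  # --- embed ----------------------------------------------------------
  emb <- stage("embed", {
    e <- train_embeddings(tok, dim = config$dim, window = config$window,
                          min_count = config$min_count, seed = config$seed)
    write_word2vec(e, out("embeddings.vec"))
    e
  })
  manifest$stages$embed <- list(output = "embeddings.vec",
                                vocab = nrow(emb$vectors),
                                dim = emb$dim, window = emb$window)

  # --- vocab ----------------------------------------------------------
  ks <- stage("vocab", {
    lex <- reference_lexicon(read_lexicon(config$bio_lexicon),
                             read_lexicon(config$ai_lexicon))
    freqs <- count_frequencies(tok)
    freqs <- freqs[names(freqs) %in% rownames(emb$vectors)]
    k <- build_keyword_set(freqs, emb, lex,
                           k_ai = config$k_ai, k_bio = config$k_bio)
    write_keyword_set(k, out("keywords.tsv"))
    k
  })
  manifest$stages$vocab <- list(output = "keywords.tsv",
                                n_ai = sum(ks$domain == "AI"),
                                n_bio = sum(ks$domain == "BIO"))

  # --- tensor ---------------------------------------------------------
  tensor <- stage("tensor", {
    binning <- time_binning(config$span_start, config$span_end,
                            config$bin_months)
    ai_ord <- cluster_order(emb, keywords(ks, "AI"), config$linkage)
    bio_ord <- cluster_order(emb, keywords(ks, "BIO"), config$linkage)
    tn <- count_tensor(tok, ai_ord, bio_ord, binning)
    write_tensor(tn, out("tensor"))
    tn
  })
  manifest$stages$tensor <- list(output = "tensor.json",
                                 dims = dim(tensor$counts))

  # --- forecast -------------------------------------------------------
  fc <- stage("forecast", {
    sweep <- window_size_sweep(tensor, config$window_sizes,
                               config$backends, seed = config$seed)
    utils::write.table(sweep, out("sweep.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nb <- dim(tensor$counts)[1]
    start <- config$forecast_start %||% nb
    run <- recurrent_forecast(tensor, start, config$forecast_horizon,
                              config$backends[1],
                              max(config$window_sizes), seed = config$seed)
    jsonlite::write_json(list(backend = run$backend, w = run$w,
                              seed = run$seed, start_bin = run$start_bin,
                              r2_trace = as.list(run$r2_trace)),
                         out("forecast_run.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    list(sweep = sweep, run = run)
  })
  manifest$stages$forecast <- list(output = "sweep.tsv",
                                   run = "forecast_run.json",
                                   best = fc$sweep[which.max(fc$sweep$mean_r2), ])

  # --- trends ---------------------------------------------------------
  tr <- stage("trends", {
    nb <- dim(tensor$counts)[1]
    doc_bins <- bin_index(tensor$binning, tok$ym)
    totals <- as.integer(table(factor(doc_bins, levels = seq_len(nb))))
    half <- max(1L, nb %/% 2L)
    recent <- (nb - half + 1L):nb
    past <- seq_len(nb - half)
    prop <- proportion_table(tensor, recent, totals, config$top_n)
    write_trend_table(prop, out("proportion.tsv"))
    grw <- if (length(past) > 0)
      growth_table(tensor, past, recent, config$threshold, config$top_n)
      else NULL
    if (!is.null(grw)) write_trend_table(grw, out("growth.tsv"))
    list(prop = prop, growth = grw)
  })
  manifest$stages$trends <- list(output = c("proportion.tsv",
                                            if (!is.null(tr$growth)) "growth.tsv"))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  invisible(manifest)
}
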