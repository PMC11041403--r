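#' Reference lexicon of domain phrases
#'
#' Holds the two reference term sets used to route keywords to a domain:
#' a large biomedical phrase list (MeSH-style) and a list of AI algorithm
#' names. Multiword phrases are normalized with the same merge rule as the
#' corpus, so `"machine learning"` becomes the token `"machine+learning"`
#' and matches merged corpus tokens.
#'
#' @param bio_terms,ai_terms character vectors of phrases.
#' @return a `reference_lexicon` object.
#' @export
reference_lexicon <- function(bio_terms, ai_terms) {
  norm <- function(x) {
    x <- unique(vapply(x, function(p) {
      t <- preprocess_text(p, merge_phrases = character())
      paste(t, collapse = "+")
    }, character(1), USE.NAMES = FALSE))
    x[nzchar(x)]
  }
  bio <- norm(bio_terms)
  ai <- norm(ai_terms)
  if (length(bio) == 0 || length(ai) == 0)
    stop("both reference term sets must be non-empty")
  structure(list(bio_terms = bio, ai_terms = ai),
            class = "reference_lexicon")
}

#' Read a one-phrase-per-line lexicon file
#'
#' @param path UTF-8 text file, one phrase per line; blank lines ignored.
#' @return character vector of phrases.
#' @export
read_lexicon <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  x[nzchar(x)]
}

#' Document frequencies of candidate terms
#'
#' Frequency is document frequency: the number of documents containing the
#' term at least once (multiple mentions in one abstract count once). This
#' matches the document-level basis of co-occurrence counting.
#'
#' @param tokcorpus a `tokenized_corpus` from [preprocess_corpus()].
#' @param candidates character vector of candidate terms; if `NULL`
#'   (default) every distinct token of the corpus is a candidate.
#' @return named integer vector, term -> document frequency.
#' @export
count_frequencies <- function(tokcorpus, candidates = NULL) {
  per_doc <- lapply(tokcorpus$tokens, unique)
  tab <- table(unlist(per_doc))
  freqs <- stats::setNames(as.integer(tab), names(tab))
  if (is.null(candidates)) return(freqs)
  if (length(candidates) == 0) stop("candidate set must be non-empty")
  out <- freqs[candidates]
  out[is.na(out)] <- 0L
  stats::setNames(as.integer(out), candidates)
}

#' Classify a term as AI or biomedical by mean cosine similarity
#'
#' Computes the mean cosine similarity of the term's vector against every
#' embedded term of each reference set and assigns `"AI"` iff the AI mean
#' strictly exceeds the biomedical mean; ties go to `"BIO"` (the larger,
#' safer axis — the audit fields expose the tie). Reference terms without
#' an embedding are dropped from the mean, not scored zero.
#'
#' @param term a token string.
#' @param emb an `embedding_table` (see [train_embeddings()]).
#' @param lex a `reference_lexicon`.
#' @return list with `domain` (`"AI"` or `"BIO"`), `mean_sim_ai`,
#'   `mean_sim_bio`.
#' @export
classify_domain <- function(term, emb, lex) {
  V <- emb$vectors
  if (!term %in% rownames(V))
    stop("term has no embedding, cannot classify: ", term)
  ai_ref <- intersect(lex$ai_terms, rownames(V))
  bio_ref <- intersect(lex$bio_terms, rownames(V))
  if (length(ai_ref) == 0 || length(bio_ref) == 0)
    stop("a reference term set is entirely out of vocabulary")
  v <- V[term, ]
  mean_sim <- function(refs) {
    R <- V[refs, , drop = FALSE]
    nr <- sqrt(rowSums(R^2))
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("term has a zero-norm embedding: ", term)
    keep <- nr > 0
    mean((R[keep, , drop = FALSE] %*% v) / (nr[keep] * nv))
  }
  a <- mean_sim(ai_ref)
  b <- mean_sim(bio_ref)
  list(domain = if (a > b) "AI" else "BIO",
       mean_sim_ai = a, mean_sim_bio = b)
}

#' Select the top-frequency keywords per domain
#'
#' Every embedded candidate is routed to a domain with [classify_domain()],
#' then the `k_ai` / `k_bio` most frequent terms are kept within each
#' domain. Frequency ties break lexicographically. A domain with fewer
#' classified terms than requested returns all of them with a warning.
#' Candidates without an embedding cannot be classified and are dropped
#' (with a warning naming how many).
#'
#' @param freqs named frequency vector from [count_frequencies()].
#' @param emb an `embedding_table`.
#' @param lex a `reference_lexicon`.
#' @param k_ai,k_bio keyword budget per domain (default 500 AI / 1000
#'   biomedical).
#' @return a `keyword_set`: `data.frame` with columns `term`, `frequency`,
#'   `domain`, `mean_sim_ai`, `mean_sim_bio`, sorted by frequency
#'   descending, with attributes `k_ai`, `k_bio`.
#' @export
build_keyword_set <- function(freqs, emb, lex, k_ai = 500, k_bio = 1000) {
  stopifnot(k_ai >= 1, k_bio >= 1)
  terms <- names(freqs)
  embedded <- terms %in% rownames(emb$vectors)
  if (any(!embedded))
    warning(sum(!embedded), " candidate term(s) lack embeddings and were dropped")
  terms <- terms[embedded]
  if (length(terms) == 0) stop("no embedded candidate terms")
  cls <- lapply(terms, classify_domain, emb = emb, lex = lex)
  df <- data.frame(
    term = terms,
    frequency = as.integer(freqs[terms]),
    domain = vapply(cls, `[[`, character(1), "domain"),
    mean_sim_ai = vapply(cls, `[[`, numeric(1), "mean_sim_ai"),
    mean_sim_bio = vapply(cls, `[[`, numeric(1), "mean_sim_bio"),
    stringsAsFactors = FALSE
  )
  take <- function(dom, k) {
    d <- df[df$domain == dom, , drop = FALSE]
    d <- d[order(-d$frequency, d$term), , drop = FALSE]
    if (nrow(d) < k)
      warning("only ", nrow(d), " ", dom, " term(s) available (requested ", k, ")")
    utils::head(d, k)
  }
  out <- rbind(take("AI", k_ai), take("BIO", k_bio))
  out <- out[order(-out$frequency, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k_ai = k_ai, k_bio = k_bio, class = c("keyword_set", "data.frame"))
}

#' Keywords of one domain, in stored order
#' @param ks a `keyword_set`.
#' @param domain `"AI"` or `"BIO"`.
#' @return character vector of terms.
#' @export
keywords <- function(ks, domain) {
  ks$term[ks$domain == domain]
}

#' Write a keyword set as TSV
#' @param ks a `keyword_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_keyword_set <- function(ks, path) {
  utils::write.table(as.data.frame(ks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
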