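#' Read a corpus of dated abstract records
#'
#' Ingests MEDLINE-style abstract records from one of three dialects:
#'
#' * `"tabular"`: TSV with header columns `doc_id`, `date` (ISO `YYYY-MM-DD`,
#'   `YYYY-MM` or `YYYY`), `title`, `abstract`.
#' * `"jsonl"`: one JSON object per line with the same keys.
#' * `"medline-xml"`: PubMed XML (`PubmedArticle` elements with `PMID`,
#'   `ArticleTitle`, `AbstractText`, `PubDate`).
#'
#' Records missing a date or a (non-whitespace) abstract are skipped and
#' counted; the skip count is returned as attribute `"skipped"`. Duplicate
#' `doc_id`s are a validation error.
#'
#' @param path path to the corpus file.
#' @param format one of `"tabular"`, `"jsonl"`, `"medline-xml"`.
#' @return a `data.frame` with columns `doc_id` (character), `ym` (integer
#'   year-month, see [parse_ym()]), `title`, `abstract`, in file order, with
#'   attribute `skipped` (integer).
#' @export
read_corpus <- function(path, format = c("tabular", "jsonl", "medline-xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file does not exist: ", path)
  raw <- switch(format,
    "tabular" = read_corpus_tabular(path),
    "jsonl" = read_corpus_jsonl(path),
    "medline-xml" = read_corpus_medline(path)
  )
  finalize_corpus(raw)
}

read_corpus_tabular <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, colClasses = "character", quote = "",
                      check.names = FALSE),
    error = function(e) stop("unparseable tabular corpus file '", path,
                             "': ", conditionMessage(e))
  )
  need <- c("doc_id", "date", "title", "abstract")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("tabular corpus missing column(s): ", paste(miss, collapse = ", "))
  df[need]
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    recs[[k]] <- tryCatch(jsonlite::fromJSON(lines[k]),
      error = function(e) {
        # byte offset of the offending line start, for the fatal format error
        off <- if (k == 1) 0L else sum(nchar(lines[seq_len(k - 1)], "bytes") + 1L)
        stop("unparseable JSON-lines corpus '", path, "' near byte offset ",
             off, ": ", conditionMessage(e))
      })
  }
  get_chr <- function(r, key) {
    v <- r[[key]]
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v[[1]])
  }
  data.frame(
    doc_id = vapply(recs, get_chr, character(1), "doc_id"),
    date = vapply(recs, get_chr, character(1), "date"),
    title = vapply(recs, get_chr, character(1), "title"),
    abstract = vapply(recs, get_chr, character(1), "abstract"),
    stringsAsFactors = FALSE
  )
}

month_name_to_num <- function(m) {
  m <- tolower(substr(trimws(m), 1, 3))
  idx <- match(m, tolower(month.abb))
  num <- suppressWarnings(as.integer(m))
  ifelse(!is.na(idx), idx, num)
}

read_corpus_medline <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) stop("unparseable MEDLINE XML '", path, "': ",
                             conditionMessage(e)))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(parent::PubmedArticle)]")
  one <- function(a) {
    txt <- function(xp) {
      n <- xml2::xml_find_first(a, xp)
      if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
    }
    pmid <- txt(".//PMID")
    title <- txt(".//ArticleTitle")
    # AbstractText may be split into labelled sections; concatenate them
    abs_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- if (length(abs_nodes) == 0) NA_character_ else
      paste(xml2::xml_text(abs_nodes), collapse = " ")
    y <- txt(".//PubDate/Year")
    m <- txt(".//PubDate/Month")
    date <- if (is.na(y)) NA_character_ else if (is.na(m)) y else {
      mn <- month_name_to_num(m)
      if (is.na(mn)) y else sprintf("%s-%02d", y, mn)
    }
    c(doc_id = pmid, date = date,
      title = if (is.na(title)) "" else title, abstract = abstract)
  }
  rows <- t(vapply(arts, one, character(4)))
  as.data.frame(rows, stringsAsFactors = FALSE)
}

finalize_corpus <- function(df) {
  ymv <- parse_ym(df$date)
  ok <- !is.na(ymv) & !is.na(df$abstract) & nzchar(trimws(df$abstract)) &
    !is.na(df$doc_id) & nzchar(df$doc_id)
  skipped <- sum(!ok)
  if (skipped > 0)
    warning(skipped, " record(s) missing date or abstract were skipped")
  out <- data.frame(
    doc_id = df$doc_id[ok],
    ym = ymv[ok],
    title = ifelse(is.na(df$title[ok]), "", df$title[ok]),
    abstract = df$abstract[ok],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$doc_id))
    stop("duplicate doc_id(s) in corpus: ",
         paste(unique(out$doc_id[duplicated(out$doc_id)])[1:5], collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}

#' Restrict a corpus to a date span
#'
#' Keeps records with `start <= date <= end` (both inclusive), preserving
#' order. The default span mirrors the semiannual analysis window of
#' January 2000 to December 2021.
#'
#' @param corpus a corpus `data.frame` from [read_corpus()].
#' @param start,end span bounds as `"YYYY-MM"` strings or ym integers.
#' @return the filtered corpus.
#' @export
filter_span <- function(corpus, start = "2000-01", end = "2021-12") {
  s <- if (is.character(start)) parse_ym(start) else as.integer(start)
  e <- if (is.character(end)) parse_ym(end) else as.integer(end)
  if (is.na(s) || is.na(e)) stop("unparseable span bound")
  if (s > e) stop("inverted span: start is after end")
  corpus[corpus$ym >= s & corpus$ym <= e, , drop = FALSE]
}

#' Tokenize and normalize text
#'
#' Lowercases, strips every character outside `[a-z+-]` (digits and
#' punctuation are removed; "-" survives because it links compound terms,
#' and "+" survives because it is the merge character), splits on
#' whitespace, drops empty fragments, and finally replaces each occurrence
#' of a multiword merge phrase with its "+"-joined single token. Longer
#' phrases are matched first so that e.g. a three-word phrase wins over a
#' two-word suffix of itself.
#'
#' The result is idempotent: re-tokenizing the space-joined token stream
#' reproduces it.
#'
#' @param text a character scalar (may be empty).
#' @param merge_phrases character vector of space-separated lowercase
#'   phrases to merge into single tokens.
#' @return character vector of tokens, each matching
#'   `^[a-z]+([-+][a-z]+)*$`.
#' @export
preprocess_text <- function(text, merge_phrases = character()) {
  if (length(text) == 0 || is.na(text)) return(character())
  x <- tolower(paste(text, collapse = " "))
  x <- gsub("[^a-z+-]+", " ", x)
  toks <- strsplit(trimws(x), "[ ]+")[[1]]
  if (length(toks) == 0 || identical(toks, "")) return(character())
  # strip stray leading/trailing separators, collapse runs ("--", "+-")
  toks <- gsub("^[-+]+|[-+]+$", "", toks)
  toks <- gsub("\\+[-+]*", "+", toks)
  toks <- gsub("-[-+]*", "-", toks)
  toks <- toks[nzchar(toks)]
  if (length(merge_phrases) > 0 && length(toks) > 0)
    toks <- merge_phrase_tokens(toks, merge_phrases)
  toks
}

# Greedy left-to-right phrase merging over a token stream, longest phrase
# first at each position.
merge_phrase_tokens <- function(toks, merge_phrases) {
  plist <- strsplit(tolower(trimws(merge_phrases)), "[ ]+")
  plist <- plist[vapply(plist, length, integer(1)) >= 2]
  if (length(plist) == 0) return(toks)
  plist <- plist[order(-vapply(plist, length, integer(1)))]
  n <- length(toks)
  out <- character(n)
  m <- 0L
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (pi in seq_along(plist)) {
      p <- plist[[pi]]
      L <- length(p)
      if (i + L - 1L <= n && all(toks[i:(i + L - 1L)] == p)) {
        hit <- L
        m <- m + 1L
        out[m] <- paste(p, collapse = "+")
        break
      }
    }
    if (hit > 0L) i <- i + hit else {
      m <- m + 1L
      out[m] <- toks[i]
      i <- i + 1L
    }
  }
  out[seq_len(m)]
}

#' Preprocess a corpus into tokenized documents
#'
#' Applies [preprocess_text()] to every record. Keyword counting is
#' abstract-based by default; set `include_title = TRUE` to prepend the
#' title to the token stream.
#'
#' @param corpus corpus `data.frame` from [read_corpus()].
#' @param merge_phrases multiword phrases to merge (see [preprocess_text()]).
#' @param include_title prepend title tokens (default `FALSE`).
#' @return a `tokenized_corpus`: list with parallel elements `doc_id`
#'   (character), `ym` (integer) and `tokens` (list of character vectors).
#' @export
preprocess_corpus <- function(corpus, merge_phrases = character(),
                              include_title = FALSE) {
  texts <- if (include_title)
    paste(corpus$title, corpus$abstract) else corpus$abstract
  toks <- lapply(texts, preprocess_text, merge_phrases = merge_phrases)
  structure(
    list(doc_id = corpus$doc_id, ym = corpus$ym, tokens = toks),
    class = "tokenized_corpus"
  )
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat("<tokenized_corpus> ", length(x$doc_id), " documents, ",
      length(unique(unlist(x$tokens))), " distinct tokens\n", sep = "")
  invisible(x)
}

#' Write a corpus as JSON-lines
#'
#' @param corpus corpus `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(k) {
    jsonlite::toJSON(list(
      doc_id = corpus$doc_id[k], date = format_ym(corpus$ym[k]),
      title = corpus$title[k], abstract = corpus$abstract[k]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
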