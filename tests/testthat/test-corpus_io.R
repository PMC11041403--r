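test_that("tabular and jsonl corpora pass through, skipping bad records", {
  td <- withr::local_tempdir()
  p <- file.path(td, "c.tsv")
  writeLines(c(
    "doc_id\tdate\ttitle\tabstract",
    "a1\t2005-03\tT one\tAlpha beta gamma.",
    "a2\t2010-11-02\tT two\tDelta epsilon.",
    "a3\t2013\tT three\tZeta eta."
  ), p)
  corpus <- read_corpus(p, "tabular")
  expect_equal(nrow(corpus), 3)
  expect_equal(corpus$doc_id, c("a1", "a2", "a3"))
  expect_equal(corpus$ym, c(2005 * 12 + 2, 2010 * 12 + 10, 2013 * 12 + 6))
  expect_equal(attr(corpus, "skipped"), 0)

  # one record without an abstract: skipped and counted
  p2 <- file.path(td, "c2.tsv")
  writeLines(c(
    "doc_id\tdate\ttitle\tabstract",
    "b1\t2005-03\tT\tSomething here.",
    "b2\t2006-01\tT\t   "
  ), p2)
  expect_warning(c2 <- read_corpus(p2, "tabular"), "skipped")
  expect_equal(nrow(c2), 1)
  expect_equal(attr(c2, "skipped"), 1)

  # same content as jsonl
  pj <- file.path(td, "c.jsonl")
  writeLines(c(
    '{"doc_id":"a1","date":"2005-03","title":"T one","abstract":"Alpha beta gamma."}',
    '{"doc_id":"a2","date":"2010-11-02","title":"T two","abstract":"Delta epsilon."}'
  ), pj)
  cj <- read_corpus(pj, "jsonl")
  expect_equal(cj$doc_id, c("a1", "a2"))
  expect_equal(cj$ym[1], corpus$ym[1])

  # broken jsonl names a byte offset
  pb <- file.path(td, "bad.jsonl")
  writeLines(c('{"doc_id":"x","date":"2001-01","abstract":"ok","title":""}',
               '{not json'), pb)
  expect_error(read_corpus(pb, "jsonl"), "byte offset")

  # duplicate ids are fatal
  pd <- file.path(td, "dup.tsv")
  writeLines(c("doc_id\tdate\ttitle\tabstract",
               "d1\t2005-03\tT\tOne.", "d1\t2005-04\tT\tTwo."), pd)
  expect_error(read_corpus(pd, "tabular"), "duplicate")
})

test_that("MEDLINE XML maps PMID, PubDate and sectioned AbstractText", {
  td <- withr::local_tempdir()
  p <- write_medline_fixture(file.path(td, "m.xml"))
  corpus <- read_corpus(p, "medline-xml")
  expect_equal(nrow(corpus), 2)
  expect_equal(corpus$doc_id, c("10000001", "10000002"))
  expect_equal(corpus$ym[1], 2021 * 12 + 2)          # 2021-03
  expect_equal(corpus$ym[2], 2019 * 12 + 6)          # year-only -> July
  expect_match(corpus$abstract[2], "Neural networks detect tumors")
  expect_match(corpus$abstract[2], "Accuracy was high")
  # round-trip through the jsonl writer and reader
  pj <- file.path(td, "m.jsonl")
  write_corpus_jsonl(corpus, pj)
  back <- read_corpus(pj, "jsonl")
  expect_equal(back$doc_id, corpus$doc_id)
  expect_equal(back$ym, corpus$ym)
  expect_equal(back$abstract, corpus$abstract)
})

test_that("preprocessing lowercases, strips noise and merges phrases", {
  # the canonical multiword merge
  expect_equal(
    preprocess_text("Machine learning improves CT-based triage in 2021.",
                    merge_phrases = "machine learning"),
    c("machine+learning", "improves", "ct-based", "triage", "in")
  )
  expect_equal(preprocess_text(""), character())
  expect_equal(preprocess_text("   \t  "), character())
  # repeated phrases merge at every occurrence
  expect_equal(
    preprocess_text("deep learning and deep learning models",
                    merge_phrases = "deep learning"),
    c("deep+learning", "and", "deep+learning", "models")
  )
  # longest phrase wins over its nested suffix
  out <- preprocess_text("a convolution neural network model",
                         merge_phrases = c("neural network",
                                           "convolution neural network"))
  expect_equal(out, c("a", "convolution+neural+network", "model"))
})

test_that("preprocessing invariants hold on generated text", {
  phrases <- c("machine learning", "neural network")
  texts <- c(
    "Machine Learning beats 500 baselines (p<0.05)!",
    "A neural network; another NEURAL NETWORK... and 42 controls",
    "state-of-the-art F1-scores, +3.2% absolute",
    "nothing special here at all"
  )
  for (tx in texts) {
    toks <- preprocess_text(tx, phrases)
    # charset invariant
    expect_true(all(grepl("^[a-z]+([-+][a-z]+)*$", toks)), info = tx)
    # idempotence: re-tokenizing the joined stream reproduces it
    expect_equal(preprocess_text(paste(toks, collapse = " "), phrases), toks,
                 info = tx)
    # merging never changes the count of non-phrase tokens
    plain <- preprocess_text(tx, character())
    n_phrase_words <- sum(vapply(strsplit(phrases, " "), function(p) {
      hits <- 0L
      for (k in seq_len(max(0, length(plain) - length(p) + 1)))
        if (all(plain[k:(k + length(p) - 1)] == p)) hits <- hits + 1L
      hits * length(p)
    }, integer(1)))
    expect_equal(sum(!grepl("\\+", toks)), length(plain) - n_phrase_words,
                 info = tx)
  }
})

test_that("filter_span keeps the inclusive window and rejects inversions", {
  rec <- data.frame(
    doc_id = paste0("d", 1:5),
    ym = c(parse_ym("1999-06"), parse_ym("1999-12"), parse_ym("2000-01"),
           parse_ym("2010-07"), parse_ym("2021-12")),
    title = "", abstract = "x", stringsAsFactors = FALSE
  )
  kept <- filter_span(rec, "2000-01", "2021-12")
  expect_equal(kept$doc_id, c("d3", "d4", "d5"))   # Jan 2000 is inclusive
  expect_error(filter_span(rec, "2021-01", "2000-01"), "inverted")

  # linear-scan oracle on a 20-record mixed fixture
  set.seed(42)
  ymv <- sample(parse_ym("1995-01"):parse_ym("2025-12"), 20)
  rec2 <- data.frame(doc_id = paste0("m", 1:20), ym = ymv, title = "",
                     abstract = "x", stringsAsFactors = FALSE)
  s <- parse_ym("2000-01"); e <- parse_ym("2021-12")
  expect_equal(nrow(filter_span(rec2, s, e)), sum(ymv >= s & ymv <= e))
})
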