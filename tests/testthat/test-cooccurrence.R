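test_that("time binning tiles the span and maps dates uniquely", {
  b <- time_binning("2000-01", "2021-12", 6)
  expect_equal(b$n_bins, 44)
  expect_equal(b$labels[1], "2000H1")
  expect_equal(b$labels[44], "2021H2")
  # every month of the span maps to exactly one bin, bins are contiguous
  idx <- bin_index(b, b$start:b$end)
  expect_equal(unname(table(idx)), rep(6L, 44), ignore_attr = TRUE)
  expect_true(all(diff(idx) %in% c(0L, 1L)))
  expect_equal(bin_index(b, parse_ym("2000-06")), 1L)  # Jan-Jun
  expect_equal(bin_index(b, parse_ym("2000-07")), 2L)  # Jul-Dec
  expect_error(bin_index(b, parse_ym("1999-12")), "outside")
  expect_error(time_binning("2000-01", "2000-05", 6), "multiple")
})

test_that("cluster_order places identical vectors adjacently", {
  m <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), a2 = c(2, 0, 0),
             b2 = c(0, 3, 0))  # a/a2 and b/b2 have identical directions
  emb <- embedding_table(m)
  co <- cluster_order(emb, c("a", "b", "a2", "b2"))
  ord <- co$order
  expect_setequal(ord, c("a", "b", "a2", "b2"))
  expect_equal(abs(which(ord == "a") - which(ord == "a2")), 1)
  expect_equal(abs(which(ord == "b") - which(ord == "b2")), 1)

  # two-term base case: single merge at their cosine distance
  co2 <- cluster_order(emb, c("a", "b"))
  expect_setequal(co2$order, c("a", "b"))
  expect_equal(co2$hclust$height, 1)  # orthogonal: 1 - cos = 1

  expect_error(cluster_order(emb, c("a", "ghost")), "ghost")
})

test_that("leaf order matches the naive O(n^3) agglomerative oracle", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(paste0("t", letters[1:n]), NULL))
    emb <- embedding_table(X)
    for (linkage in c("average", "complete")) {
      co <- cluster_order(emb, rownames(X), linkage)
      nrm <- X / sqrt(rowSums(X^2))
      D <- 1 - nrm %*% t(nrm)
      diag(D) <- 0
      ora <- naive_agglom(D, linkage)
      expect_equal(co$hclust$merge, ora$merge, info = paste(seed, linkage))
      expect_equal(co$hclust$height, ora$height, tolerance = 1e-10)
      expect_equal(co$order, rownames(X)[ora$order],
                   info = paste(seed, linkage))
    }
  }
})

test_that("count_tensor counts document-level co-occurrence per bin", {
  b <- time_binning("2001-01", "2001-12", 6)
  tok <- structure(list(
    doc_id = c("d1", "d2", "d3"),
    ym = c(parse_ym("2001-02"), parse_ym("2001-03"), parse_ym("2001-09")),
    tokens = list(
      c("neural+network", "treats", "cancer", "cancer"),
      c("plain", "text", "only"),
      c("svm", "cancer")
    )), class = "tokenized_corpus")
  tn <- count_tensor(tok, c("neural+network", "svm"), c("cancer", "gene"), b)
  expect_equal(tn$counts["2001H1", "neural+network", "cancer"], 1L)
  expect_equal(tn$counts["2001H2", "svm", "cancer"], 1L)
  expect_equal(sum(tn$counts), 2L)                 # repeated mention counts once
  expect_equal(sum(tn$counts["2001H1", , ]), 1L)   # d2 contributes nothing
  expect_error(count_tensor(tok, c("neural+network"), c("cancer"),
                            time_binning("2001-01", "2001-06", 6)),
               "outside")
})

test_that("count_tensor equals the brute-force oracle and its invariants", {
  sc <- trend_scenario(k_ai = 5, k_bio = 7, bins = 4, base_rate = 2,
                       seed = 21, background_docs = 5)
  gen <- generate_corpus(sc)
  tok <- preprocess_corpus(gen$records, gen$merge_phrases)
  tn <- count_tensor(tok, gen$ai_order, gen$bio_order, gen$binning)
  ora <- oracle_tensor(tok$tokens, tok$ym, gen$ai_order, gen$bio_order,
                       gen$binning)
  expect_identical(tn$counts, ora)

  # permuting document order leaves the tensor unchanged
  set.seed(1)
  perm <- sample(length(tok$doc_id))
  tokp <- structure(list(doc_id = tok$doc_id[perm], ym = tok$ym[perm],
                         tokens = tok$tokens[perm]),
                    class = "tokenized_corpus")
  tnp <- count_tensor(tokp, gen$ai_order, gen$bio_order, gen$binning)
  expect_identical(tnp$counts, tn$counts)

  # a single bin's slice equals counting that bin's documents alone
  keep <- bin_index(gen$binning, tok$ym) == 2L
  tok2 <- structure(list(doc_id = tok$doc_id[keep], ym = tok$ym[keep],
                         tokens = tok$tokens[keep]),
                    class = "tokenized_corpus")
  tn2 <- count_tensor(tok2, gen$ai_order, gen$bio_order, gen$binning)
  expect_equal(tn2$counts[2, , ], tn$counts[2, , ])

  # per-bin cap: no cell exceeds its bin's document count
  nb <- gen$binning$n_bins
  docs_per_bin <- tabulate(bin_index(gen$binning, tok$ym), nb)
  for (t in seq_len(nb))
    expect_true(all(tn$counts[t, , ] <= docs_per_bin[t]))
})

test_that("log_heat maps counts onto decades", {
  expect_equal(log_heat(matrix(c(0, 9, 99, 999), 2)),
               matrix(c(0, 1, 2, 3), 2))
  expect_error(log_heat(matrix(-1)), "nonnegative")
})

test_that("tensors round-trip through the TSV + JSON format", {
  sc <- trend_scenario(k_ai = 4, k_bio = 5, bins = 3, base_rate = 3, seed = 8)
  tn <- generate_tensor(sc)$tensor
  td <- withr::local_tempdir()
  write_tensor(tn, file.path(td, "tn"))
  back <- read_tensor(file.path(td, "tn"))
  expect_identical(back$counts, tn$counts)
  expect_equal(back$ai_order, tn$ai_order)
  expect_equal(back$bio_order, tn$bio_order)
  expect_equal(back$binning$labels, tn$binning$labels)
})
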