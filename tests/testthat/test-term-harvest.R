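test_that("the dictionary automaton reports overlapping and nested hits", {
  m <- build_matcher(c("糖尿病", "肾病", "糖尿病肾病"))
  hits <- match_text(m, "糖尿病肾病")
  key <- match_set_key(hits)
  expect_setequal(key, c("糖尿病@1@3", "肾病@4@5", "糖尿病肾病@1@5"))

  # duplicates in the lexicon collapse to one pattern set
  m2 <- build_matcher(c("糖尿病", "糖尿病", "肾病", "糖尿病肾病"))
  expect_identical(match_set_key(match_text(m2, "糖尿病肾病")), key)

  expect_error(build_matcher(character()), "empty lexicon")
  expect_error(build_matcher(c("糖尿病", "")), "non-empty")
})

test_that("automaton match set equals the naive substring scan on random cases", {
  set.seed(11)
  alphabet <- c("糖", "尿", "病", "肾", "炎", "a", "b")
  rand_str <- function(lo, hi) {
    paste(sample(alphabet, sample(lo:hi, 1), replace = TRUE), collapse = "")
  }
  for (case in 1:200) {
    lexicon <- unique(replicate(sample(3:10, 1), rand_str(1, 4)))
    text <- rand_str(10, 40)
    got <- match_text(build_matcher(lexicon), text)
    want <- oracle_substring_scan(lexicon, text)
    expect_identical(match_set_key(got), match_set_key(want),
                     label = paste("case", case, text))
  }
})

test_that("scan_corpus counts documents, not occurrences", {
  m <- build_matcher(c("糖尿病", "低血糖"))
  corpus <- list(
    list(doc_id = "d1", text = "糖尿病……糖尿病又见糖尿病"),
    list(doc_id = "d2", text = "糖尿病与低血糖"),
    list(doc_id = "d3", text = "无关内容")
  )
  cands <- scan_corpus(corpus, m)
  dm <- cands[cands$surface == "糖尿病", ]
  expect_identical(dm$doc_frequency, 2L)   # thrice in d1 still counts once
  expect_identical(dm$doc_ids[[1]], c("d1", "d2"))
  expect_identical(cands[cands$surface == "低血糖", ]$doc_frequency, 1L)

  expect_identical(nrow(scan_corpus(list(), m)), 0L)
  expect_error(scan_corpus(list(list(doc_id = "d", text = "x"),
                                list(doc_id = "d", text = "y")), m),
               "duplicate doc_id")
})

test_that("planted corpus document frequencies are recovered exactly", {
  cp <- make_corpus(seed = 3)
  cands <- scan_corpus(cp$corpus, build_matcher(cp$lexicon))
  for (i in seq_len(nrow(cp$truth))) {
    surface <- cp$truth$surface[i]
    row <- cands[cands$surface == surface, ]
    expect_identical(row$doc_frequency, cp$truth$doc_frequency[i],
                     label = surface)
  }
})

test_that("grade/degree and stoplist exclusion removes exactly those surfaces", {
  mk <- function(surfaces) {
    scan_corpus(lapply(seq_along(surfaces), function(i) {
      list(doc_id = paste0("d", i), text = surfaces[i])
    }), build_matcher(surfaces))
  }
  cands <- mk(c("1级", "糖尿病", "全部"))
  kept <- exclude_pattern_terms(cands)
  expect_identical(kept$surface, "糖尿病")

  # programmatic construction: every numeral x suffix combination dies,
  # all ten disease names survive
  numerals <- c(as.character(1:9), "一", "三", "十")
  grades <- as.vector(outer(numerals, c("级", "期", "度", "型"), paste0))
  diseases <- paste0(c("甲", "乙", "丙", "丁", "戊", "己", "庚", "辛", "壬",
                       "癸"), "病")
  cands2 <- mk(c(grades, diseases))
  kept2 <- exclude_pattern_terms(cands2)
  expect_setequal(kept2$surface, diseases)
})

test_that("frequency filter is conjunctive and boundary-inclusive", {
  doc_ids <- function(k) sprintf("d%02d", seq_len(k))
  cands <- structure(
    data.frame(surface = c("甲", "乙", "丙"),
               doc_frequency = c(3L, 2L, 5L),
               merged_into = NA_character_, stringsAsFactors = FALSE),
    class = c("cdmo_candidates", "data.frame"))
  cands$doc_ids <- list(doc_ids(3), doc_ids(2), doc_ids(5))
  cands$lexicon_sources <- rep(list(character()), 3)

  kept <- frequency_filter(cands, lexicon_presence = c("甲", "乙"))
  expect_identical(kept$surface, "甲")  # df=3 in lexicon kept (boundary)
  # df=2 in lexicon dropped; df=5 not in lexicon dropped

  # brute-force set filter over a generated 100-candidate table
  set.seed(5)
  n <- 100
  surf <- sprintf("词%03d", seq_len(n))
  freq <- sample(0:6, n, replace = TRUE)
  big <- structure(
    data.frame(surface = surf, doc_frequency = freq,
               merged_into = NA_character_, stringsAsFactors = FALSE),
    class = c("cdmo_candidates", "data.frame"))
  big$doc_ids <- lapply(freq, doc_ids)
  big$lexicon_sources <- rep(list(character()), n)
  lex <- sample(surf, 60)
  for (min_docs in 1:5) {
    got <- frequency_filter(big, lex, min_docs)$surface
    want <- surf[surf %in% lex & freq >= min_docs]
    expect_identical(got, want)
  }
  # monotone in min_docs: raising the threshold never adds a candidate
  prev <- frequency_filter(big, lex, 1L)$surface
  for (min_docs in 2:6) {
    cur <- frequency_filter(big, lex, min_docs)$surface
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("synonym merging is union-find over shared names and listed pairs", {
  mk <- function(surfaces) {
    out <- structure(
      data.frame(surface = surfaces, doc_frequency = 1L,
                 merged_into = NA_character_, stringsAsFactors = FALSE),
      class = c("cdmo_candidates", "data.frame"))
    out$doc_ids <- lapply(seq_along(surfaces), function(i) paste0("d", i))
    out$lexicon_sources <- rep(list(character()), length(surfaces))
    out
  }
  # two spellings sharing one English name merge into one group
  cands <- mk(c("黑棘皮症", "黑棘皮病", "糖尿病"))
  merged <- merge_synonyms(cands, english_names = list(
    "黑棘皮症" = "acanthosis nigricans",
    "黑棘皮病" = "acanthosis nigricans"))
  expect_identical(sum(is.na(merged$merged_into)), 2L)
  canon <- merged$surface[!is.na(merged$merged_into)]
  expect_identical(enc2utf8(merged$merged_into[!is.na(merged$merged_into)]),
                   enc2utf8("黑棘皮病"))  # bytewise-smallest member wins
  # the canonical row aggregates the group's documents
  crow <- merged[merged$surface == "黑棘皮病", ]
  expect_identical(crow$doc_frequency, 2L)

  # no shared names, no pairs: everyone stays canonical
  lone <- merge_synonyms(mk(c("甲", "乙", "丙")))
  expect_true(all(is.na(lone$merged_into)))

  # chained pairs form a single connected component
  chain <- merge_synonyms(mk(c("a", "b", "c", "d")),
                          synonym_pairs = list(c("a", "b"), c("b", "c")))
  expect_identical(sum(is.na(chain$merged_into)), 2L)  # {a,b,c} + {d}
  expect_setequal(chain$merged_into[chain$surface %in% c("b", "c")], "a")

  # random instances against an igraph connected-components oracle
  set.seed(13)
  for (case in 1:20) {
    n <- sample(5:12, 1)
    surfaces <- sprintf("t%02d", seq_len(n))
    pairs <- replicate(sample(0:6, 1), sample(surfaces, 2), simplify = FALSE)
    got <- merge_synonyms(mk(surfaces), synonym_pairs = pairs)
    gr <- igraph::graph_from_data_frame(
      if (length(pairs)) do.call(rbind, pairs) else
        matrix(character(), ncol = 2),
      directed = FALSE, vertices = surfaces)
    comp <- igraph::components(gr)$membership
    want_canon <- vapply(surfaces, function(s) {
      min(surfaces[comp == comp[[s]]])
    }, character(1))
    got_canon <- ifelse(is.na(got$merged_into), got$surface, got$merged_into)
    expect_identical(unname(got_canon), unname(want_canon[got$surface]))
  }
})

test_that("harvest report arithmetic matches the stated retention figures", {
  rep <- harvest_report(47598, 47598, 7000, 6816)
  expect_identical(rep$retention_pct, 14.32)
  expect_identical(harvest_report(200, 200, 40, 37)$retention_pct, 18.50)
  expect_identical(harvest_report(10, 10, 10, 10)$retention_pct, 100.00)
  expect_error(harvest_report(0, 0, 0, 0), "positive")
  expect_error(harvest_report(10, 11, 11, 11), "non-increasing")
})

test_that("the full pipeline recovers the planted true terms exactly", {
  cp <- make_corpus(seed = 1)
  h <- harvest_terms(cp$corpus, cp$lexicon, cp$lexicon_presence,
                     english_names = cp$english_names)
  expect_identical(sort(enc2utf8(h$candidates$surface), method = "radix"),
                   cp$survivors)
  # stage counts are consistent and non-increasing
  expect_true(h$report$n_scanned >= h$report$n_after_exclusion)
  expect_true(h$report$n_after_exclusion >= h$report$n_after_filter)
  expect_identical(h$report$n_after_merge, nrow(h$candidates))
  # noise terms never survive
  noise <- cp$truth$surface[cp$truth$excluded]
  expect_length(intersect(h$candidates$surface, noise), 0L)
})

test_that("corpus and lexicon files round-trip", {
  td <- withr::local_tempdir()
  cp <- make_corpus(seed = 2)
  f <- file.path(td, "corpus.jsonl")
  write_corpus_jsonl(cp$corpus, f)
  back <- read_corpus_jsonl(f)
  expect_identical(length(back), length(cp$corpus))
  expect_identical(enc2utf8(back[[3]]$text), enc2utf8(cp$corpus[[3]]$text))

  h <- harvest_terms(cp$corpus, cp$lexicon, cp$lexicon_presence)
  fc <- file.path(td, "cands.csv")
  write_candidates_csv(h$candidates, fc)
  flat <- utils::read.csv(fc, stringsAsFactors = FALSE, encoding = "UTF-8")
  expect_identical(enc2utf8(flat$surface), enc2utf8(h$candidates$surface))
  expect_identical(flat$doc_frequency, h$candidates$doc_frequency)
})
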