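# Term harvesting: dictionary-automaton extraction from a Chinese corpus,
# grade/degree exclusion, lexicon-presence + document-frequency filtering and
# union-find synonym merging.

#' Build an Aho-Corasick matcher over a lexicon
#'
#' Constructs the classic trie-with-failure-links automaton so that every
#' lexicon entry is recognized as a substring of a scanned text in a single
#' pass, including overlapping and nested hits. Duplicate lexicon entries are
#' collapsed. Both lexicon and text are matched on raw Unicode codepoints
#' after NFC-style normalization is left to the caller (Chinese clinical text
#' has no case).
#'
#' @param lexicon Non-empty character vector of non-empty surface strings.
#' @return An object of class `cdmo_matcher`.
#' @export
#' @examples
#' m <- build_matcher(c("糖尿病", "肾病"))
#' match_text(m, "糖尿病肾病")
build_matcher <- function(lexicon) {
  lexicon <- unique(as.character(lexicon))
  if (!length(lexicon)) stop("empty lexicon", call. = FALSE)
  if (any(!nzchar(lexicon)) || anyNA(lexicon)) {
    stop("lexicon entries must be non-empty strings", call. = FALSE)
  }
  lexicon <- enc2utf8(lexicon)
  # trie: children[[node]] is a named integer vector (char -> node id)
  children <- list(integer())
  outputs <- list(integer())
  for (pi in seq_along(lexicon)) {
    chars <- strsplit(lexicon[[pi]], "", fixed = TRUE)[[1]]
    node <- 1L
    for (ch in chars) {
      nxt <- children[[node]][ch]
      if (is.na(nxt)) {
        children[[length(children) + 1L]] <- integer()
        outputs[[length(outputs) + 1L]] <- integer()
        nxt <- length(children)
        children[[node]][ch] <- nxt
      }
      node <- as.integer(nxt)
    }
    outputs[[node]] <- c(outputs[[node]], pi)
  }
  # failure links by breadth-first traversal
  fail <- rep(1L, length(children))
  queue <- as.integer(children[[1L]])
  head <- 1L
  while (head <= length(queue)) {
    u <- queue[head]
    head <- head + 1L
    for (ch in names(children[[u]])) {
      v <- as.integer(children[[u]][ch])
      f <- fail[u]
      while (f != 1L && is.na(children[[f]][ch])) f <- fail[f]
      cand <- children[[f]][ch]
      fail[v] <- if (!is.na(cand) && as.integer(cand) != v) as.integer(cand) else 1L
      outputs[[v]] <- c(outputs[[v]], outputs[[fail[v]]])
      queue <- c(queue, v)
    }
  }
  structure(list(children = children, fail = fail, outputs = outputs,
                 patterns = lexicon),
            class = "cdmo_matcher")
}

#' Scan one text with a matcher
#'
#' All occurrences of all lexicon entries, overlapping hits included.
#'
#' @param matcher A [build_matcher()] automaton.
#' @param text String to scan.
#' @return `data.frame` with columns `surface`, `start`, `end` (1-based
#'   codepoint positions), ordered by `end` then `surface`.
#' @export
match_text <- function(matcher, text) {
  stopifnot(inherits(matcher, "cdmo_matcher"))
  text <- enc2utf8(as.character(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  node <- 1L
  hit_pat <- integer()
  hit_end <- integer()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    while (node != 1L && is.na(matcher$children[[node]][ch])) {
      node <- matcher$fail[node]
    }
    nxt <- matcher$children[[node]][ch]
    node <- if (is.na(nxt)) 1L else as.integer(nxt)
    out <- matcher$outputs[[node]]
    if (length(out)) {
      hit_pat <- c(hit_pat, out)
      hit_end <- c(hit_end, rep(i, length(out)))
    }
  }
  surface <- matcher$patterns[hit_pat]
  res <- data.frame(surface = surface,
                    start = hit_end - nchar(surface) + 1L,
                    end = hit_end,
                    stringsAsFactors = FALSE)
  res[order(res$end, res$surface), , drop = FALSE]
}

#' Harvest term candidates from a corpus
#'
#' One candidate per distinct surface, with document-level (not occurrence
#' level) bookkeeping: `doc_ids` lists every document containing at least one
#' occurrence and `doc_frequency` is the number of such documents, so a term
#' seen twice in one document still counts once.
#'
#' @param corpus List of documents, each a list with fields `doc_id`, `text`
#'   and optionally `source` (see [read_corpus_jsonl()]).
#' @param matcher A [build_matcher()] automaton.
#' @param lexicon_sources Optional named list mapping a surface to its
#'   lexicon provenance labels (subset of dictionary, termonline,
#'   encyclopedia, manual).
#' @return A candidate table of class `cdmo_candidates`: a `data.frame` with
#'   columns `surface`, `doc_frequency`, list-columns `doc_ids` and
#'   `lexicon_sources`, and `merged_into` (`NA` until [merge_synonyms()]).
#' @export
scan_corpus <- function(corpus, matcher, lexicon_sources = list()) {
  ids <- vapply(corpus, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus", call. = FALSE)
  hits <- new.env(parent = emptyenv())
  for (d in corpus) {
    m <- match_text(matcher, d$text)
    for (sf in unique(m$surface)) {
      hits[[sf]] <- c(hits[[sf]], d$doc_id)
    }
  }
  surfaces <- utf8_sort(ls(hits))
  doc_ids <- lapply(surfaces, function(sf) utf8_sort(unique(hits[[sf]])))
  candidates(
    surface = surfaces,
    doc_ids = doc_ids,
    lexicon_sources = lapply(surfaces, function(sf) {
      as.character(lexicon_sources[[sf]] %||% character())
    })
  )
}

# internal constructor keeping the invariant doc_frequency == |doc_ids|
candidates <- function(surface, doc_ids, lexicon_sources = NULL,
                       merged_into = NULL) {
  if (is.null(lexicon_sources)) {
    lexicon_sources <- rep(list(character()), length(surface))
  }
  if (is.null(merged_into)) merged_into <- rep(NA_character_, length(surface))
  out <- data.frame(surface = as.character(surface),
                    doc_frequency = vapply(doc_ids, length, integer(1)),
                    merged_into = merged_into,
                    stringsAsFactors = FALSE)
  out$doc_ids <- doc_ids
  out$lexicon_sources <- lexicon_sources
  class(out) <- c("cdmo_candidates", "data.frame")
  out
}

# grade/degree surfaces: Arabic or Chinese numerals followed by one of
# 级 (grade), 期 (stage), 度 (degree), 型 (type), as the entire surface
grade_degree_pattern <- function() {
  "^[0-9零〇一二三四五六七八九十百]+[级期度型]$"
}

#' Exclude grade/degree terms and stoplist entries
#'
#' Drops candidates whose whole surface is a grade or degree expression
#' (Arabic or Chinese numeral followed by 级/期/度/型, e.g.
#' "1级" grade 1, "1期" stage 1) and candidates on the stoplist
#' (seeded with "全部", "all"). All other candidates pass untouched.
#'
#' @param cands A `cdmo_candidates` table.
#' @param stoplist Character vector of exact surfaces to drop.
#' @return The filtered candidate table.
#' @export
exclude_pattern_terms <- function(cands, stoplist = default_stoplist()) {
  drop <- grepl(grade_degree_pattern(), cands$surface, perl = TRUE) |
    cands$surface %in% stoplist
  out <- cands[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname exclude_pattern_terms
#' @export
default_stoplist <- function() "全部"

#' Lexicon-presence and document-frequency filter
#'
#' Keeps a candidate iff its surface has a corresponding entry in the
#' supplied lexicon-presence set AND it appears in at least `min_docs`
#' distinct documents. Both conditions are conjunctive; the document count is
#' the pre-merge `doc_frequency`.
#'
#' @param cands A `cdmo_candidates` table.
#' @param lexicon_presence Character vector of surfaces with a dictionary,
#'   terminology-service or encyclopedia entry.
#' @param min_docs Minimum number of distinct documents (default 3).
#' @return The filtered candidate table.
#' @export
frequency_filter <- function(cands, lexicon_presence, min_docs = 3L) {
  stopifnot(min_docs >= 1L)
  keep <- cands$surface %in% lexicon_presence & cands$doc_frequency >= min_docs
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge literal synonyms into groups
#'
#' Union-find over the relation "share at least one English name" together
#' with explicitly listed synonym pairs (e.g. two Chinese spellings sharing
#' the English name "acanthosis nigricans"). Within each group the
#' lexicographically smallest surface (bytewise UTF-8 order, locale
#' independent) becomes canonical; the others get `merged_into` set to it.
#' The canonical row re-aggregates the group's `doc_ids`, `doc_frequency`
#' and `lexicon_sources`.
#'
#' @param cands A `cdmo_candidates` table.
#' @param english_names Named list mapping a surface to its English names.
#' @param synonym_pairs List of length-2 character vectors; pairs whose
#'   members are not both candidates are ignored.
#' @return The candidate table with merge groups resolved.
#' @export
merge_synonyms <- function(cands, english_names = list(),
                           synonym_pairs = list()) {
  n <- nrow(cands)
  if (n == 0L) return(cands)
  idx <- stats::setNames(seq_len(n), cands$surface)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  # shared English names
  en_owner <- new.env(parent = emptyenv())
  for (sf in cands$surface) {
    for (en in tolower(english_names[[sf]] %||% character())) {
      prev <- en_owner[[en]]
      if (is.null(prev)) en_owner[[en]] <- idx[[sf]]
      else union_(prev, idx[[sf]])
    }
  }
  for (pair in synonym_pairs) {
    a <- idx[pair[[1]]]; b <- idx[pair[[2]]]
    if (!is.na(a) && !is.na(b)) union_(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- cands
  for (r in unique(root)) {
    members <- which(root == r)
    if (length(members) == 1L) next
    canon <- members[order(enc2utf8(cands$surface[members]), method = "radix")][1L]
    others <- setdiff(members, canon)
    out$merged_into[others] <- cands$surface[canon]
    out$doc_ids[[canon]] <- utf8_sort(unique(unlist(cands$doc_ids[members])))
    out$doc_frequency[canon] <- length(out$doc_ids[[canon]])
    out$lexicon_sources[[canon]] <-
      utf8_sort(unique(unlist(cands$lexicon_sources[members])))
  }
  out
}

#' Harvest bookkeeping report
#'
#' Counts along the exclude -> filter -> merge pipeline plus the retention
#' percentage, `100 * retained / recognized` rounded to two decimals (e.g.
#' 6,816 retained out of 47,598 recognized is 14.32).
#'
#' @param n_recognized Raw match count (> 0).
#' @param n_after_exclusion,n_after_filter,n_after_merge Stage counts; must
#'   be non-increasing in this order and bounded by `n_recognized`.
#' @return An object of class `cdmo_harvest_report`.
#' @export
harvest_report <- function(n_recognized, n_after_exclusion, n_after_filter,
                           n_after_merge) {
  if (n_recognized <= 0L) stop("n_recognized must be positive", call. = FALSE)
  counts <- c(n_recognized, n_after_exclusion, n_after_filter, n_after_merge)
  if (any(diff(counts) > 0)) {
    stop("stage counts must be non-increasing", call. = FALSE)
  }
  structure(
    list(n_scanned = n_recognized,
         n_after_exclusion = n_after_exclusion,
         n_after_filter = n_after_filter,
         n_after_merge = n_after_merge,
         retention_pct = round(100 * n_after_merge / n_recognized, 2)),
    class = "cdmo_harvest_report"
  )
}

#' @export
print.cdmo_harvest_report <- function(x, ...) {
  cat(sprintf("Harvest: %d recognized -> %d after exclusion -> %d after filter -> %d after merge (%.2f%% retained)\n",
              x$n_scanned, x$n_after_exclusion, x$n_after_filter,
              x$n_after_merge, x$retention_pct))
  invisible(x)
}

#' Run the whole harvesting pipeline
#'
#' scan -> exclude grade/degree + stoplist -> lexicon-presence and
#' document-frequency filter -> synonym merge, returning both the surviving
#' candidates and the stage-count report. "Retained" counts unmerged
#' (canonical) candidates after merging.
#'
#' @inheritParams scan_corpus
#' @param lexicon Character vector of matcher surfaces.
#' @param lexicon_presence Surfaces with a lexicon entry; defaults to
#'   `lexicon`.
#' @inheritParams frequency_filter
#' @inheritParams exclude_pattern_terms
#' @inheritParams merge_synonyms
#' @return List with elements `candidates` (survivors, canonical rows only)
#'   and `report` (a [harvest_report()]).
#' @export
harvest_terms <- function(corpus, lexicon, lexicon_presence = lexicon,
                          min_docs = 3L, stoplist = default_stoplist(),
                          english_names = list(), synonym_pairs = list(),
                          lexicon_sources = list()) {
  matcher <- build_matcher(lexicon)
  cands <- scan_corpus(corpus, matcher, lexicon_sources)
  n0 <- nrow(cands)
  cands <- exclude_pattern_terms(cands, stoplist)
  n1 <- nrow(cands)
  cands <- frequency_filter(cands, lexicon_presence, min_docs)
  n2 <- nrow(cands)
  merged <- merge_synonyms(cands, english_names, synonym_pairs)
  survivors <- merged[is.na(merged$merged_into), , drop = FALSE]
  rownames(survivors) <- NULL
  n3 <- nrow(survivors)
  report <- if (n0 > 0L) harvest_report(n0, n1, n2, n3) else NULL
  list(candidates = survivors, report = report)
}

# -- file formats -------------------------------------------------------------

#' Read a JSONL corpus
#'
#' One document per line: `{"doc_id": ..., "text": ..., "source": ...}`.
#'
#' @param path File path.
#' @return List of document records.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    d <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    list(doc_id = d$doc_id, text = d$text, source = d$source %||% "")
  })
}

#' Write a JSONL corpus
#' @param corpus List of document records.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, text = d$text,
                          source = d$source %||% ""), auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read a lexicon TSV (surface, source)
#' @param path File path.
#' @return `data.frame` with columns `surface`, `source`.
#' @export
read_lexicon_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    encoding = "UTF-8", colClasses = "character")
}

#' Write candidates to CSV
#'
#' Columns `surface`, `doc_frequency`, `sources` (semicolon-joined),
#' `merged_into`; list-columns are flattened.
#'
#' @param cands A `cdmo_candidates` table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_candidates_csv <- function(cands, path) {
  flat <- data.frame(
    surface = cands$surface,
    doc_frequency = cands$doc_frequency,
    sources = vapply(cands$lexicon_sources, paste, character(1), collapse = ";"),
    merged_into = cands$merged_into,
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
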