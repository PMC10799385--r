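# Ontology-knowledge injection for question answering: BM25 retrieval of
# concept definitions as evidence, prompt assembly, and ROUGE-1/2/L scoring
# of generated answers against references.

#' Tokenize text for retrieval and scoring
#'
#' `char_bigram` (default, suited to Chinese with no word boundaries) emits
#' overlapping character bigrams, or the single character for a length-1
#' text; `word` splits on whitespace and punctuation. Deterministic.
#'
#' @param text Character scalar.
#' @param mode `"char_bigram"` or `"word"`.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize("糖尿病")  # "糖尿" "尿病"
tokenize <- function(text, mode = c("char_bigram", "word")) {
  mode <- match.arg(mode)
  text <- enc2utf8(as.character(text))
  if (mode == "word") {
    toks <- strsplit(text, "[\\s[:punct:]]+", perl = TRUE)[[1]]
    return(toks[nzchar(toks)])
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(character())
  if (n == 1L) return(chars)
  paste0(chars[-n], chars[-1L])
}

#' Retrieval configuration
#'
#' `k1` is BM25's term-frequency saturation parameter and `b` its document
#' length normalization; defaults are the standard Okapi values 1.5 and
#' 0.75. `n` is the number of evidence definitions injected into a prompt
#' (default 3).
#'
#' @param n Evidence count (>= 1).
#' @param k1 Saturation parameter (> 0).
#' @param b Length-normalization parameter in \eqn{[0, 1]}.
#' @param tokenizer `"char_bigram"` or `"word"`.
#' @return An object of class `cdmo_retrieval_config`.
#' @export
retrieval_config <- function(n = 3L, k1 = 1.5, b = 0.75,
                             tokenizer = c("char_bigram", "word")) {
  tokenizer <- match.arg(tokenizer)
  stopifnot(n >= 1L, k1 > 0, b >= 0, b <= 1)
  structure(list(n = as.integer(n), k1 = k1, b = b, tokenizer = tokenizer),
            class = "cdmo_retrieval_config")
}

#' Rank documents against a query with Okapi BM25
#'
#' Standard BM25 with the smoothed non-negative IDF
#' \eqn{\log(1 + (N - df + 0.5)/(df + 0.5))}. All documents are returned,
#' sorted by descending score with ties broken by input order.
#'
#' @param query Query string.
#' @param docs Non-empty list of evidence documents, each a list with
#'   fields `concept_iri` and `text`.
#' @param config A [retrieval_config()].
#' @return `data.frame` with columns `concept_iri`, `text`, `score`,
#'   ordered best-first.
#' @export
bm25_rank <- function(query, docs, config = retrieval_config()) {
  if (!length(docs)) stop("empty document list", call. = FALSE)
  toks <- lapply(docs, function(d) tokenize(d$text, config$tokenizer))
  qtok <- unique(tokenize(query, config$tokenizer))
  N <- length(docs)
  dl <- vapply(toks, length, integer(1))
  avgdl <- mean(dl)
  if (avgdl == 0) avgdl <- 1
  df_count <- vapply(qtok, function(t) {
    sum(vapply(toks, function(tt) t %in% tt, logical(1)))
  }, numeric(1))
  idf <- log(1 + (N - df_count + 0.5) / (df_count + 0.5))
  scores <- vapply(seq_len(N), function(i) {
    tf <- vapply(qtok, function(t) sum(toks[[i]] == t), numeric(1))
    denom <- tf + config$k1 * (1 - config$b + config$b * dl[i] / avgdl)
    sum(idf * tf * (config$k1 + 1) / ifelse(denom == 0, 1, denom))
  }, numeric(1))
  ord <- order(-scores, seq_len(N))
  data.frame(
    concept_iri = vapply(docs, function(d) d$concept_iri %||% "", character(1))[ord],
    text = vapply(docs, `[[`, character(1), "text")[ord],
    score = scores[ord],
    stringsAsFactors = FALSE
  )
}

#' Retrieve the most relevant concept definitions as evidence
#'
#' BM25-ranks every defined concept's definition text against the question
#' and returns the top `config$n`; if fewer definitions exist, all are
#' returned.
#'
#' @param question Question string.
#' @param graph A `cdmo_ontology` with at least one defined concept.
#' @param config A [retrieval_config()].
#' @return List of evidence documents (fields `concept_iri`, `text`,
#'   `score`), best-first, length `min(n, available)`.
#' @export
retrieve_evidence <- function(question, graph, config = retrieval_config()) {
  docs <- list()
  for (iri in names(graph$concepts)) {
    con <- graph$concepts[[iri]]
    if (!is.null(con$definition)) {
      docs[[length(docs) + 1L]] <- list(concept_iri = iri,
                                        text = con$definition$text)
    }
  }
  if (!length(docs)) {
    stop("ontology has no concept definitions to retrieve from", call. = FALSE)
  }
  ranked <- bm25_rank(question, docs, config)
  top <- utils::head(ranked, config$n)
  lapply(seq_len(nrow(top)), function(i) {
    list(concept_iri = top$concept_iri[i], text = top$text[i],
         score = top$score[i])
  })
}

#' Assemble the model input prompt
#'
#' Exact template `Question: {Q}, Evidences: {D1}, ..., {Dn}` with evidence
#' texts joined by `", "` in retrieval order; no truncation (length handling
#' is the caller's concern). With zero evidences the evidence slot is empty.
#'
#' @param question Question string.
#' @param evidences List of evidence documents (or character vector of
#'   texts), ordered as retrieved.
#' @return Prompt string.
#' @export
build_prompt <- function(question, evidences) {
  texts <- if (is.character(evidences)) evidences else
    vapply(evidences, `[[`, character(1), "text")
  paste0("Question: ", question, ", Evidences: ",
         paste(texts, collapse = ", "))
}

#' Parse a prompt back into question and evidence list
#'
#' Inverse of [build_prompt()] for prompts whose question contains no
#' `", Evidences: "` marker.
#'
#' @param prompt Prompt string.
#' @return List with `question` and `evidences` (character vector).
#' @export
parse_prompt <- function(prompt) {
  if (!startsWith(prompt, "Question: ")) {
    stop("not a recognized prompt", call. = FALSE)
  }
  rest <- substring(prompt, nchar("Question: ") + 1L)
  i <- regexpr(", Evidences: ", rest, fixed = TRUE)
  if (i < 0) stop("not a recognized prompt", call. = FALSE)
  q <- substr(rest, 1L, i - 1L)
  ev <- substring(rest, i + nchar(", Evidences: "))
  evs <- if (nzchar(ev)) strsplit(ev, ", ", fixed = TRUE)[[1]] else character()
  list(question = q, evidences = evs)
}

ngrams <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  if (k <= 0L) return(character())
  vapply(seq_len(k), function(i) paste(tokens[i:(i + n - 1L)], collapse = "\u1f"),
         character(1))
}

overlap_f1 <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  ta <- table(a); tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  ov <- sum(pmin(ta[shared], tb[shared]))
  p <- ov / length(a)
  r <- ov / length(b)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
      else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-1, ROUGE-2 and ROUGE-L scores
#'
#' N-gram overlap F1 for ROUGE-1/2 (clipped counts) and
#' longest-common-subsequence F1 for ROUGE-L, computed over character-level
#' units by default — standard practice for Chinese, where word boundaries
#' are unmarked. Identical texts score 1 on all three; texts sharing no
#' units score 0.
#'
#' @param candidate Generated text.
#' @param reference Reference text.
#' @param mode `"char"` (default) or `"word"` units.
#' @return An object of class `cdmo_rouge` with fields `rouge1`, `rouge2`,
#'   `rougeL`, each an F1 in \eqn{[0, 1]}.
#' @export
rouge_scores <- function(candidate, reference, mode = c("char", "word")) {
  mode <- match.arg(mode)
  units <- function(x) {
    x <- enc2utf8(as.character(x))
    if (mode == "char") {
      u <- strsplit(x, "", fixed = TRUE)[[1]]
      u[!grepl("^\\s$", u)]
    } else {
      tokenize(x, "word")
    }
  }
  uc <- units(candidate); ur <- units(reference)
  if (!length(uc) || !length(ur)) {
    stop("candidate and reference must tokenize to at least one unit",
         call. = FALSE)
  }
  l <- lcs_length(uc, ur)
  pl <- l / length(uc); rl <- l / length(ur)
  structure(list(
    rouge1 = overlap_f1(uc, ur),
    rouge2 = overlap_f1(ngrams(uc, 2L), ngrams(ur, 2L)),
    rougeL = if (pl + rl == 0) 0 else 2 * pl * rl / (pl + rl)
  ), class = "cdmo_rouge")
}

#' @export
print.cdmo_rouge <- function(x, ...) {
  cat(sprintf("ROUGE-1 %.4f  ROUGE-2 %.4f  ROUGE-L %.4f\n",
              x$rouge1, x$rouge2, x$rougeL))
  invisible(x)
}

#' Score a JSONL file of QA pairs
#'
#' Each line: `{"question": ..., "reference_answer": ...,
#' "generated_answer": ...}`. Pairs without a generated answer are skipped.
#'
#' @param path JSONL file path.
#' @param mode ROUGE unit mode.
#' @return `data.frame` with one row per scored pair plus columns `rouge1`,
#'   `rouge2`, `rougeL`, and a `"means"` attribute with the three averages.
#' @export
score_qa_pairs <- function(path, mode = "char") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- list()
  for (l in lines) {
    d <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    if (is.null(d$generated_answer)) next
    sc <- rouge_scores(d$generated_answer, d$reference_answer, mode)
    rows[[length(rows) + 1L]] <- data.frame(
      question = d$question, rouge1 = sc$rouge1, rouge2 = sc$rouge2,
      rougeL = sc$rougeL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(question = character(),
                                      rouge1 = numeric(), rouge2 = numeric(),
                                      rougeL = numeric())
  attr(out, "means") <- c(rouge1 = mean(out$rouge1), rouge2 = mean(out$rouge2),
                          rougeL = mean(out$rougeL))
  out
}

#' Random train/dev/test split of QA pairs
#'
#' Generic 80/20 split with a dev set carved out of training (20% of
#' training by default), reproducible under a seed.
#'
#' @param n Number of pairs.
#' @param train_frac Fraction assigned to training before the dev carve-out.
#' @param dev_frac_of_train Fraction of training reassigned to dev.
#' @param seed Integer seed.
#' @return Character vector of length `n` with values `"train"`, `"dev"`,
#'   `"test"`.
#' @export
split_qa_dataset <- function(n, train_frac = 0.8, dev_frac_of_train = 0.2,
                             seed = 1L) {
  stopifnot(n >= 1L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(n)
  n_train_all <- round(train_frac * n)
  train_all <- idx[seq_len(n_train_all)]
  n_dev <- round(dev_frac_of_train * n_train_all)
  dev <- train_all[seq_len(n_dev)]
  out <- rep("test", n)
  out[train_all] <- "train"
  out[dev] <- "dev"
  out
}
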