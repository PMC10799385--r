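# Independent oracles: deliberately naive re-implementations used to check
# the package's algorithms. They share no code with the implementation.

# recursive depth-first reachability over parent links (reflexive)
oracle_reachable <- function(graph, a, b, seen = character()) {
  if (a == b) return(TRUE)
  if (a %in% seen) return(FALSE)
  for (p in graph$concepts[[a]]$parents) {
    if (oracle_reachable(graph, p, b, c(seen, a))) return(TRUE)
  }
  FALSE
}

# all-positions fixed substring scan: every (pattern, start) occurrence
oracle_substring_scan <- function(lexicon, text) {
  out <- list()
  tchars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(tchars)
  for (pat in unique(lexicon)) {
    pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
    k <- length(pchars)
    if (k > n) next
    for (s in seq_len(n - k + 1L)) {
      if (all(tchars[s:(s + k - 1L)] == pchars)) {
        out[[length(out) + 1L]] <- data.frame(
          surface = pat, start = s, end = s + k - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

match_set_key <- function(df) {
  sort(paste(enc2utf8(df$surface), df$start, df$end, sep = "@"))
}

# random DAG as an ontology: node i may take parents among 1..i-1
oracle_random_dag <- function(n, p_edge = 0.15) {
  concepts <- lapply(seq_len(n), function(i) {
    parents <- character()
    if (i > 1L) {
      pick <- which(stats::runif(i - 1L) < p_edge)
      parents <- sprintf("node:%03d", pick)
    }
    concept(sprintf("node:%03d", i), sprintf("概念%03d", i),
            labels_en = sprintf("node %03d", i), parents = parents)
  })
  has_parent <- vapply(concepts, function(c) length(c$parents) > 0L, logical(1))
  ontology(concepts, roots = sprintf("node:%03d", which(!has_parent)))
}

# ---- tuple-at-a-time naive rule evaluator ----------------------------------

oracle_resolve_class <- function(tbox, ref) {
  for (iri in names(tbox$concepts)) {
    con <- tbox$concepts[[iri]]
    ok <- tolower(gsub("_", " ", ref)) %in% tolower(con$labels_en) ||
      tolower(ref) %in% tolower(con$labels_en) ||
      ref == con$label_zh || ref == iri
    if (ok) return(iri)
  }
  stop("oracle: unresolved class ", ref)
}

oracle_unify <- function(binding, term, value) {
  if (term$type == "var") {
    if (!is.null(binding[[term$name]])) {
      prev <- binding[[term$name]]
      if (!identical(as.character(prev), as.character(value))) return(NULL)
      return(binding)
    }
    binding[[term$name]] <- value
    return(binding)
  }
  if (term$type == "ind") {
    if (identical(term$name, as.character(value))) return(binding) else return(NULL)
  }
  if (isTRUE(as.numeric(value) == term$value)) binding else NULL
}

oracle_atom_bindings <- function(kb, atom, binding) {
  out <- list()
  if (atom$kind == "class") {
    iri <- oracle_resolve_class(kb$tbox, atom$predicate)
    for (ind in names(kb$individuals)) {
      types <- kb$individuals[[ind]]
      if (any(vapply(types, function(t) oracle_reachable(kb$tbox, t, iri),
                     logical(1)))) {
        b <- oracle_unify(binding, atom$args[[1]], ind)
        if (!is.null(b)) out[[length(out) + 1L]] <- b
      }
    }
    return(out)
  }
  if (atom$kind == "builtin") {
    vals <- numeric()
    for (t in atom$args) {
      v <- if (t$type == "var") binding[[t$name]] else t$value
      if (is.null(v)) stop("oracle: unbound builtin arg")
      vals <- c(vals, as.numeric(v))
    }
    ok <- switch(atom$predicate,
                 greaterThanOrEqual = vals[1] >= vals[2],
                 greaterThan = vals[1] > vals[2],
                 lessThanOrEqual = vals[1] <= vals[2],
                 lessThan = vals[1] < vals[2],
                 equal = vals[1] == vals[2],
                 notEqual = vals[1] != vals[2])
    if (isTRUE(ok)) return(list(binding))
    return(list())
  }
  da <- kb$data_assertions
  if (atom$predicate %in% da$property) {
    rows <- da[da$property == atom$predicate, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      b <- oracle_unify(binding, atom$args[[1]], rows$subject[i])
      if (is.null(b)) next
      b <- oracle_unify(b, atom$args[[2]], rows$value[i])
      if (!is.null(b)) out[[length(out) + 1L]] <- b
    }
    return(out)
  }
  oa <- kb$object_assertions
  rows <- oa[oa$property == atom$predicate, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    b <- oracle_unify(binding, atom$args[[1]], rows$subject[i])
    if (is.null(b)) next
    b <- oracle_unify(b, atom$args[[2]], rows$object[i])
    if (!is.null(b)) out[[length(out) + 1L]] <- b
  }
  out
}

oracle_rule_bindings <- function(kb, atoms, binding = list()) {
  if (!length(atoms)) return(list(binding))
  first <- oracle_atom_bindings(kb, atoms[[1]], binding)
  out <- list()
  for (b in first) {
    out <- c(out, oracle_rule_bindings(kb, atoms[-1], b))
  }
  out
}

# naive fixpoint: re-scan all rules x all bindings each pass
oracle_forward_chain <- function(kb, rules) {
  okey <- function(p, s, o) paste("object", p, s, o, sep = "|")
  tkey <- function(i, cl) paste("type", i, cl, sep = "|")
  known <- character()
  for (ind in names(kb$individuals)) {
    for (t in kb$individuals[[ind]]) known <- c(known, tkey(ind, t))
  }
  oa <- kb$object_assertions
  known <- c(known, vapply(seq_len(nrow(oa)), function(i) {
    okey(oa$property[i], oa$subject[i], oa$object[i])
  }, character(1)))
  derived <- character()
  repeat {
    new_found <- FALSE
    for (rule in rules) {
      for (b in oracle_rule_bindings(kb, rule$antecedent)) {
        for (atom in rule$consequent) {
          val <- function(t) if (t$type == "var") as.character(b[[t$name]])
                             else t$name
          if (atom$kind == "class") {
            iri <- oracle_resolve_class(kb$tbox, atom$predicate)
            k <- tkey(val(atom$args[[1]]), iri)
            if (!k %in% known) {
              known <- c(known, k); derived <- c(derived, k)
              kb$individuals[[val(atom$args[[1]])]] <-
                c(kb$individuals[[val(atom$args[[1]])]], iri)
              new_found <- TRUE
            }
          } else {
            s <- val(atom$args[[1]]); o <- val(atom$args[[2]])
            k <- okey(atom$predicate, s, o)
            if (!k %in% known) {
              known <- c(known, k); derived <- c(derived, k)
              kb$object_assertions <- rbind(
                kb$object_assertions,
                data.frame(property = atom$predicate, subject = s, object = o,
                           stringsAsFactors = FALSE))
              new_found <- TRUE
            }
          }
        }
      }
    }
    if (!new_found) break
  }
  sort(derived)
}

derived_keys <- function(result) {
  sort(vapply(result$derived, function(a) {
    if (a$kind == "type") paste("type", a$individual, a$class, sep = "|")
    else paste("object", a$property, a$subject, a$object, sep = "|")
  }, character(1)))
}

# ---- direct BM25 formula (term-by-term, no shared code) --------------------

oracle_bm25 <- function(query_tokens, doc_token_lists, k1, b) {
  N <- length(doc_token_lists)
  dl <- vapply(doc_token_lists, length, numeric(1))
  avgdl <- mean(dl)
  if (avgdl == 0) avgdl <- 1
  vapply(seq_len(N), function(i) {
    s <- 0
    for (term in unique(query_tokens)) {
      df <- sum(vapply(doc_token_lists,
                       function(d) term %in% d, logical(1)))
      idf <- log(1 + (N - df + 0.5) / (df + 0.5))
      f <- sum(doc_token_lists[[i]] == term)
      if (f > 0) {
        s <- s + idf * (f * (k1 + 1)) /
          (f + k1 * (1 - b + b * dl[i] / avgdl))
      }
    }
    s
  }, numeric(1))
}

# ---- canonical ontology comparison -----------------------------------------

canonical_concept <- function(con) {
  ann <- con$annotations
  ann_str <- if (length(ann)) {
    paste(sort(paste(enc2utf8(names(ann)), enc2utf8(ann), sep = "=")),
          collapse = ";")
  } else ""
  list(iri = con$iri,
       label_zh = enc2utf8(con$label_zh),
       labels_en = sort(enc2utf8(con$labels_en)),
       synonyms_zh = sort(enc2utf8(con$synonyms_zh)),
       definition = if (is.null(con$definition)) NULL else
         list(text = enc2utf8(con$definition$text),
              source = con$definition$source),
       annotations = ann_str,
       parents = sort(con$parents))
}

expect_ontology_equal <- function(a, b) {
  expect_setequal(names(a$concepts), names(b$concepts))
  for (iri in names(a$concepts)) {
    expect_equal(canonical_concept(a$concepts[[iri]]),
                 canonical_concept(b$concepts[[iri]]),
                 label = paste("concept", iri))
  }
  expect_setequal(a$roots, b$roots)
  expect_setequal(names(a$properties), names(b$properties))
  for (nm in names(a$properties)) {
    pa <- a$properties[[nm]]; pb <- b$properties[[nm]]
    expect_equal(pa$kind, pb$kind)
    expect_equal(sort(pa$domain), sort(pb$domain))
    expect_equal(sort(pa$range), sort(pb$range))
    expect_equal(pa$parent, pb$parent)
  }
  invisible(TRUE)
}

edge_key <- function(df) sort(paste(df$child_iri, df$parent_iri, sep = "->"))
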