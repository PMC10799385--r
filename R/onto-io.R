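# Ontology serialization: a named-class OWL subset in Turtle, RDF/XML and a
# JSON dialect mirroring the concept/property fields exactly.
#
# Modeled vocabulary: owl:Class, rdfs:subClassOf between named classes (with
# rdfs:subClassOf owl:Thing marking declared roots), rdfs:label with zh/en
# language tags, skos:altLabel, skos:definition plus a definition-source
# annotation, owl:ObjectProperty / owl:AnnotationProperty with
# rdfs:subPropertyOf, rdfs:domain, rdfs:range. Anything else — in particular
# class expressions and restrictions (blank nodes) — is skipped with a
# warning, never an error.

BASE_NS <- c(
  rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
  owl   = "http://www.w3.org/2002/07/owl#",
  skos  = "http://www.w3.org/2004/02/skos/core#",
  cdmo  = "http://example.org/cdmo#",
  cdmop = "http://example.org/cdmo/property#",
  cdmoa = "http://example.org/cdmo/annotation#"
)

ns_for_prefix <- function(prefix) {
  if (prefix %in% names(BASE_NS)) BASE_NS[[prefix]]
  else paste0("http://example.org/ns/", prefix, "#")
}

expand_curie <- function(x) {
  i <- regexpr(":", x, fixed = TRUE)
  prefix <- substr(x, 1L, i - 1L)
  local <- substr(x, i + 1L, nchar(x))
  paste0(ns_for_prefix(prefix), local)
}

compact_iri <- function(full, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(full, ns)) return(paste0(p, ":", substring(full, nchar(ns) + 1L)))
  }
  full
}

#' Load an ontology from a file
#'
#' Reads the named-class OWL subset from Turtle, RDF/XML or the package's
#' JSON dialect. Labels (`rdfs:label` with `zh`/`en` tags), synonyms
#' (`skos:altLabel`), definitions (`skos:definition` plus a source
#' annotation), subclass axioms between named classes and property
#' declarations are populated; non-simple axioms (class expressions, blank
#' nodes) are skipped with a warning. A cyclic is_a relation after load is a
#' validation error naming one cycle.
#'
#' @param path File path.
#' @param format `"turtle"`, `"rdfxml"` or `"json"`; the default guesses from
#'   the file extension (`.ttl`, `.rdf`/`.owl`/`.xml`, `.json`).
#' @return A `cdmo_ontology`.
#' @export
load_ontology <- function(path, format = c("auto", "turtle", "rdfxml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read ontology file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ttl = "turtle", rdf = , owl = , xml = "rdfxml",
                     json = "json",
                     stop("cannot guess format of '", path, "'", call. = FALSE))
  }
  switch(format,
         turtle = ontology_from_triples(parse_turtle(path)),
         rdfxml = ontology_from_triples(parse_rdfxml(path)),
         json   = ontology_from_json(path))
}

#' Save an ontology to a file
#'
#' Output is deterministic: concepts and properties are sorted by IRI/name,
#' so repeated saves of the same graph are byte-identical, and a saved file
#' re-loads to an equal graph.
#'
#' @param graph A valid `cdmo_ontology`.
#' @inheritParams load_ontology
#' @return `path`, invisibly.
#' @export
save_ontology <- function(graph, path, format = c("auto", "turtle", "rdfxml", "json")) {
  format <- match.arg(format)
  validate_ontology(graph)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ttl = "turtle", rdf = , owl = , xml = "rdfxml",
                     json = "json",
                     stop("cannot guess format of '", path, "'", call. = FALSE))
  }
  switch(format,
         turtle = write_turtle(graph, path),
         rdfxml = write_rdfxml(graph, path),
         json   = write_ontology_json(graph, path))
  invisible(path)
}

# -- JSON dialect -------------------------------------------------------------

concept_to_list <- function(con) {
  list(
    iri = con$iri, label_zh = con$label_zh,
    labels_en = as.list(con$labels_en),
    synonyms_zh = as.list(con$synonyms_zh),
    definition = if (is.null(con$definition)) NULL else
      list(text = con$definition$text, source = con$definition$source),
    annotations = as.list(con$annotations),
    parents = as.list(con$parents)
  )
}

write_ontology_json <- function(graph, path) {
  obj <- list(
    concepts = lapply(graph$concepts[order(names(graph$concepts))],
                      concept_to_list),
    properties = lapply(graph$properties[order(names(graph$properties))],
                        function(p) {
                          list(name_zh = p$name_zh, name_en = p$name_en,
                               kind = p$kind, parent = p$parent,
                               domain = as.list(p$domain),
                               range = as.list(p$range))
                        }),
    roots = as.list(sort(graph$roots))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
}

ontology_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  concepts <- lapply(obj$concepts, function(c) {
    def <- if (is.null(c$definition)) NULL else
      definition_record(c$definition$text, c$definition$source)
    ann <- character()
    if (length(c$annotations)) {
      ann <- vapply(c$annotations, as.character, character(1))
    }
    concept(c$iri, c$label_zh,
            labels_en = unlist(c$labels_en) %||% character(),
            synonyms_zh = unlist(c$synonyms_zh) %||% character(),
            definition = def, annotations = ann,
            parents = unlist(c$parents) %||% character())
  })
  properties <- lapply(obj$properties, function(p) {
    property_def(p$name_zh, p$name_en %||% "", p$kind, parent = p$parent,
                 domain = unlist(p$domain) %||% character(),
                 range = unlist(p$range) %||% character())
  })
  ontology(concepts, properties, roots = unlist(obj$roots) %||% character())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# -- Turtle -------------------------------------------------------------------

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

ttl_lit <- function(x, lang = NULL) {
  if (is.null(lang)) sprintf('"%s"', ttl_escape(x))
  else sprintf('"%s"@%s', ttl_escape(x), lang)
}

write_turtle <- function(graph, path) {
  used <- unique(sub(":.*$", "", c(names(graph$concepts), "cdmop", "cdmoa")))
  prefixes <- c("rdf", "rdfs", "owl", "skos", used)
  prefixes <- unique(prefixes)
  lines <- c(
    vapply(sort(prefixes),
           function(p) sprintf("@prefix %s: <%s> .", p, ns_for_prefix(p)),
           character(1)),
    ""
  )
  for (iri in sort(names(graph$concepts))) {
    con <- graph$concepts[[iri]]
    stmts <- c("a owl:Class",
               sprintf("rdfs:label %s", ttl_lit(con$label_zh, "zh")))
    for (en in con$labels_en) {
      stmts <- c(stmts, sprintf("rdfs:label %s", ttl_lit(en, "en")))
    }
    for (syn in con$synonyms_zh) {
      stmts <- c(stmts, sprintf("skos:altLabel %s", ttl_lit(syn, "zh")))
    }
    if (!is.null(con$definition)) {
      stmts <- c(stmts,
                 sprintf("skos:definition %s", ttl_lit(con$definition$text)),
                 sprintf("cdmoa:definition_source %s",
                         ttl_lit(con$definition$source)))
    }
    if (length(con$annotations)) {
      for (k in sort(names(con$annotations))) {
        stmts <- c(stmts, sprintf("cdmoa:%s %s", k,
                                  ttl_lit(con$annotations[[k]])))
      }
    }
    if (iri %in% graph$roots) {
      stmts <- c(stmts, "rdfs:subClassOf owl:Thing")
    }
    for (p in sort(con$parents)) {
      stmts <- c(stmts, sprintf("rdfs:subClassOf %s", p))
    }
    lines <- c(lines,
               paste0(iri, " ", paste(stmts, collapse = " ;\n    "), " ."),
               "")
  }
  for (nm in sort(names(graph$properties))) {
    pr <- graph$properties[[nm]]
    subj <- paste0("cdmop:", nm)
    type <- if (pr$kind == "object") "owl:ObjectProperty" else "owl:AnnotationProperty"
    stmts <- c(paste("a", type),
               sprintf("rdfs:label %s", ttl_lit(pr$name_zh, "zh")))
    if (nzchar(pr$name_en)) {
      stmts <- c(stmts, sprintf("rdfs:label %s", ttl_lit(pr$name_en, "en")))
    }
    if (!is.null(pr$parent)) {
      stmts <- c(stmts, sprintf("rdfs:subPropertyOf cdmop:%s", pr$parent))
    }
    for (d in sort(pr$domain)) stmts <- c(stmts, sprintf("rdfs:domain %s", d))
    for (r in sort(pr$range)) stmts <- c(stmts, sprintf("rdfs:range %s", r))
    lines <- c(lines, paste0(subj, " ", paste(stmts, collapse = " ;\n    "), " ."),
               "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
}

# Tokenizer for the Turtle subset: IRIREFs, prefixed names, language-tagged
# string literals and punctuation. Blank-node brackets are tokenized so the
# parser can skip the whole bracketed group.
tokenize_turtle <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  tokens <- list()
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == '"') {
      i <- i + 1L
      buf <- character()
      while (i <= n && chars[i] != '"') {
        if (chars[i] == "\\" && i < n) {
          nxt <- chars[i + 1L]
          buf <- c(buf, switch(nxt, n = "\n", t = "\t", nxt))
          i <- i + 2L
        } else {
          buf <- c(buf, chars[i])
          i <- i + 1L
        }
      }
      if (i > n) stop("unterminated string literal in Turtle input", call. = FALSE)
      i <- i + 1L
      lang <- NULL
      if (i <= n && chars[i] == "@") {
        j <- i + 1L
        while (j <= n && grepl("[A-Za-z-]", chars[j])) j <- j + 1L
        lang <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
        i <- j
      } else if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        i <- i + 2L  # datatype IRI follows; consume it as one token below
        j <- i
        while (j <= n && !chars[j] %in% c(" ", "\t", "\n", "\r", ";", ",", ".")) {
          j <- j + 1L
        }
        i <- j
      }
      push("literal", structure(paste(buf, collapse = ""), lang = lang))
      next
    }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRIREF in Turtle input", call. = FALSE)
      push("iriref", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      # '.' inside a prefixed name never occurs in this subset's vocabulary
      push("punct", ch)
      i <- i + 1L
      next
    }
    # bare token: prefixed name, @prefix keyword, or 'a'
    j <- i
    while (j <= n &&
           !chars[j] %in% c(" ", "\t", "\n", "\r", ";", ",", "[", "]", "(", ")",
                            '"', "<")) {
      j <- j + 1L
    }
    word <- paste(chars[i:(j - 1L)], collapse = "")
    # a trailing '.' terminates the statement rather than the name
    if (grepl("\\.$", word)) {
      word <- sub("\\.$", "", word)
      if (nzchar(word)) push("name", word)
      push("punct", ".")
    } else {
      push("name", word)
    }
    i <- j
    next
  }
  tokens
}

parse_turtle <- function(path) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  tokens <- tokenize_turtle(text)
  prefixes <- BASE_NS
  triples <- list()
  skipped <- 0L
  i <- 1L
  n <- length(tokens)
  tok <- function(k) if (k <= n) tokens[[k]] else NULL
  while (i <= n) {
    t <- tok(i)
    if (t$type == "name" && t$value %in% c("@prefix", "PREFIX")) {
      pfx <- sub(":$", "", tok(i + 1L)$value)
      prefixes[[pfx]] <- tok(i + 2L)$value
      i <- i + 3L
      if (!is.null(tok(i)) && tok(i)$type == "punct" && tok(i)$value == ".") {
        i <- i + 1L
      }
      next
    }
    # subject
    subj <- t$value
    i <- i + 1L
    repeat {
      pred <- tok(i)
      if (is.null(pred)) stop("truncated Turtle statement", call. = FALSE)
      pname <- if (pred$type == "name" && pred$value == "a") "rdf:type" else pred$value
      i <- i + 1L
      repeat {
        ob <- tok(i)
        if (is.null(ob)) stop("truncated Turtle statement", call. = FALSE)
        if (ob$type == "punct" && ob$value == "[") {
          depth <- 1L
          i <- i + 1L
          while (depth > 0L) {
            b <- tok(i)
            if (is.null(b)) stop("unbalanced blank node", call. = FALSE)
            if (b$type == "punct" && b$value == "[") depth <- depth + 1L
            if (b$type == "punct" && b$value == "]") depth <- depth - 1L
            i <- i + 1L
          }
          skipped <- skipped + 1L
        } else if (ob$type == "literal") {
          triples[[length(triples) + 1L]] <- list(
            s = subj, p = pname, o = as.character(ob$value),
            lang = attr(ob$value, "lang"), literal = TRUE)
          i <- i + 1L
        } else {
          triples[[length(triples) + 1L]] <- list(
            s = subj, p = pname, o = ob$value, lang = NULL, literal = FALSE)
          i <- i + 1L
        }
        sep <- tok(i)
        if (!is.null(sep) && sep$type == "punct" && sep$value == ",") {
          i <- i + 1L
        } else break
      }
      sep <- tok(i)
      if (!is.null(sep) && sep$type == "punct" && sep$value == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        nxt <- tok(i)
        if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ".") {
          i <- i + 1L
          break
        }
      } else {
        if (!is.null(sep) && sep$type == "punct" && sep$value == ".") i <- i + 1L
        break
      }
    }
  }
  if (skipped > 0L) {
    warning(skipped, " non-simple axiom(s) (blank nodes) skipped on load",
            call. = FALSE)
  }
  list(triples = triples, prefixes = prefixes)
}

# Assemble an ontology from parsed triples (Turtle or RDF/XML path).
ontology_from_triples <- function(parsed) {
  triples <- parsed$triples
  if (!length(triples)) {
    warning("empty ontology file: no classes declared", call. = FALSE)
    return(ontology())
  }
  s <- vapply(triples, `[[`, character(1), "s")
  p <- vapply(triples, `[[`, character(1), "p")
  o <- vapply(triples, `[[`, character(1), "o")
  lang <- vapply(triples, function(t) t$lang %||% "", character(1))
  lit <- vapply(triples, `[[`, logical(1), "literal")

  class_iris <- sort(unique(s[p == "rdf:type" & o == "owl:Class"]))
  obj_props <- sort(unique(s[p == "rdf:type" & o == "owl:ObjectProperty"]))
  ann_props <- sort(unique(s[p == "rdf:type" & o == "owl:AnnotationProperty"]))

  roots <- character()
  concepts <- lapply(class_iris, function(iri) {
    mine <- s == iri
    zh <- o[mine & p == "rdfs:label" & lang == "zh"]
    en <- o[mine & p == "rdfs:label" & lang == "en"]
    syn <- o[mine & p == "skos:altLabel"]
    def_text <- o[mine & p == "skos:definition"]
    def_src <- o[mine & p == "cdmoa:definition_source"]
    def <- if (length(def_text)) {
      definition_record(def_text[[1]],
                        if (length(def_src)) def_src[[1]] else "manual")
    }
    sup <- o[mine & p == "rdfs:subClassOf" & !lit]
    if ("owl:Thing" %in% sup) roots <<- c(roots, iri)
    sup <- setdiff(sup, "owl:Thing")
    ann_rows <- mine & lit & startsWith(p, "cdmoa:") &
      p != "cdmoa:definition_source"
    ann <- stats::setNames(o[ann_rows], sub("^cdmoa:", "", p[ann_rows]))
    if (length(zh) == 0L) {
      stop("class ", iri, " has no zh label", call. = FALSE)
    }
    concept(iri, zh[[1]], labels_en = en, synonyms_zh = syn,
            definition = def, annotations = ann, parents = sup)
  })

  mk_prop <- function(iri, kind) {
    mine <- s == iri
    zh <- o[mine & p == "rdfs:label" & lang == "zh"]
    en <- o[mine & p == "rdfs:label" & lang == "en"]
    parent <- o[mine & p == "rdfs:subPropertyOf"]
    dom <- o[mine & p == "rdfs:domain"]
    rng <- o[mine & p == "rdfs:range"]
    nm <- if (length(zh)) zh[[1]] else sub("^cdmop:", "", iri)
    property_def(nm, if (length(en)) en[[1]] else "", kind,
                 parent = if (length(parent)) sub("^cdmop:", "", parent[[1]]),
                 domain = dom, range = rng)
  }
  properties <- c(lapply(obj_props, mk_prop, kind = "object"),
                  lapply(ann_props, mk_prop, kind = "annotation"))

  # unreferenced subjects with subClassOf but no declared type are still
  # concepts in permissive inputs; restrict to declared classes per contract
  ontology(concepts, properties, roots = unique(roots))
}

# -- RDF/XML ------------------------------------------------------------------

write_rdfxml <- function(graph, path) {
  used <- unique(sub(":.*$", "", names(graph$concepts)))
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = BASE_NS[["rdf"]], "xmlns:rdfs" = BASE_NS[["rdfs"]],
    "xmlns:owl" = BASE_NS[["owl"]], "xmlns:skos" = BASE_NS[["skos"]],
    "xmlns:cdmoa" = BASE_NS[["cdmoa"]]
  )
  for (iri in sort(names(graph$concepts))) {
    con <- graph$concepts[[iri]]
    cls <- xml2::xml_add_child(doc, "owl:Class", "rdf:about" = expand_curie(iri))
    lbl <- xml2::xml_add_child(cls, "rdfs:label", con$label_zh)
    xml2::xml_set_attr(lbl, "xml:lang", "zh")
    for (en in con$labels_en) {
      lbl <- xml2::xml_add_child(cls, "rdfs:label", en)
      xml2::xml_set_attr(lbl, "xml:lang", "en")
    }
    for (syn in con$synonyms_zh) {
      a <- xml2::xml_add_child(cls, "skos:altLabel", syn)
      xml2::xml_set_attr(a, "xml:lang", "zh")
    }
    if (!is.null(con$definition)) {
      xml2::xml_add_child(cls, "skos:definition", con$definition$text)
      xml2::xml_add_child(cls, "cdmoa:definition_source", con$definition$source)
    }
    if (length(con$annotations)) {
      for (k in sort(names(con$annotations))) {
        node <- xml2::xml_add_child(cls, paste0("cdmoa:", k),
                                    con$annotations[[k]])
      }
    }
    if (iri %in% graph$roots) {
      xml2::xml_add_child(cls, "rdfs:subClassOf",
                          "rdf:resource" = paste0(BASE_NS[["owl"]], "Thing"))
    }
    for (par in sort(con$parents)) {
      xml2::xml_add_child(cls, "rdfs:subClassOf",
                          "rdf:resource" = expand_curie(par))
    }
  }
  for (nm in sort(names(graph$properties))) {
    pr <- graph$properties[[nm]]
    tag <- if (pr$kind == "object") "owl:ObjectProperty" else "owl:AnnotationProperty"
    node <- xml2::xml_add_child(doc, tag,
                                "rdf:about" = paste0(BASE_NS[["cdmop"]], nm))
    lbl <- xml2::xml_add_child(node, "rdfs:label", pr$name_zh)
    xml2::xml_set_attr(lbl, "xml:lang", "zh")
    if (nzchar(pr$name_en)) {
      lbl <- xml2::xml_add_child(node, "rdfs:label", pr$name_en)
      xml2::xml_set_attr(lbl, "xml:lang", "en")
    }
    if (!is.null(pr$parent)) {
      xml2::xml_add_child(node, "rdfs:subPropertyOf",
                          "rdf:resource" = paste0(BASE_NS[["cdmop"]], pr$parent))
    }
    for (d in sort(pr$domain)) {
      xml2::xml_add_child(node, "rdfs:domain", "rdf:resource" = expand_curie(d))
    }
    for (r in sort(pr$range)) {
      xml2::xml_add_child(node, "rdfs:range", "rdf:resource" = expand_curie(r))
    }
  }
  xml2::write_xml(doc, path)
}

parse_rdfxml <- function(path) {
  doc <- xml2::read_xml(path)
  # prefix table for compacting resource IRIs back to CURIEs
  prefixes <- BASE_NS
  compact <- function(full) {
    if (startsWith(full, "http://example.org/ns/")) {
      rest <- substring(full, nchar("http://example.org/ns/") + 1L)
      return(sub("#", ":", rest, fixed = TRUE))
    }
    compact_iri(full, prefixes)
  }
  triples <- list()
  add <- function(s, p, o, lang = NULL, literal = FALSE) {
    triples[[length(triples) + 1L]] <<- list(s = s, p = p, o = o, lang = lang,
                                             literal = literal)
  }
  kids <- xml2::xml_children(doc)
  skipped <- 0L
  for (node in kids) {
    tag <- xml2::xml_name(node, ns = xml2::xml_ns(doc))
    about <- xml2::xml_attr(node, "about")
    if (is.na(about)) next
    subj <- compact(about)
    type <- switch(tag,
                   "owl:Class" = "owl:Class",
                   "owl:ObjectProperty" = "owl:ObjectProperty",
                   "owl:AnnotationProperty" = "owl:AnnotationProperty",
                   NA_character_)
    if (is.na(type)) { skipped <- skipped + 1L; next }
    add(subj, "rdf:type", type)
    for (ch in xml2::xml_children(node)) {
      pname <- xml2::xml_name(ch, ns = xml2::xml_ns(doc))
      res <- xml2::xml_attr(ch, "resource")
      if (!is.na(res)) {
        add(subj, pname, compact(res))
      } else if (length(xml2::xml_children(ch))) {
        skipped <- skipped + 1L  # nested class expression
      } else {
        add(subj, pname, xml2::xml_text(ch),
            lang = xml2::xml_attr(ch, "lang"), literal = TRUE)
      }
    }
  }
  if (skipped > 0L) {
    warning(skipped, " non-simple node(s) skipped on RDF/XML load",
            call. = FALSE)
  }
  # normalize NA langs to NULL
  triples <- lapply(triples, function(t) {
    if (!is.null(t$lang) && is.na(t$lang)) t$lang <- NULL
    t
  })
  list(triples = triples, prefixes = prefixes)
}
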