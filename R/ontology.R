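#' @keywords internal
"_PACKAGE"

# locale-independent (bytewise UTF-8) ordering helpers; radix sorting
# requires explicitly marked encodings
utf8_sort <- function(x) sort(enc2utf8(x), method = "radix")
utf8_order <- function(...) order(..., method = "radix")

# -- constructors -------------------------------------------------------------

#' Create a definition record
#'
#' A concept definition together with its provenance. Sources form a closed
#' set and carry a fixed preference order used by [select_definition()]:
#' terminology services are preferred over encyclopedic text, which is
#' preferred over phenotype and regulatory vocabularies, with manually written
#' definitions as the fallback.
#'
#' @param text Definition text (non-empty string).
#' @param source One of `"termonline"`, `"baidu"`, `"CHPO"`, `"MedDRA"`,
#'   `"manual"`.
#' @return An object of class `cdmo_definition`.
#' @export
#' @examples
#' definition_record("A metabolic disorder of glucose regulation.", "manual")
definition_record <- function(text, source) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  source <- match.arg(source, definition_sources())
  structure(list(text = text, source = source), class = "cdmo_definition")
}

#' @rdname definition_record
#' @export
definition_sources <- function() {
  c("termonline", "baidu", "CHPO", "MedDRA", "manual")
}

#' Create an ontology concept
#'
#' A bilingual ontology class: an opaque IRI, a Chinese preferred label,
#' English names, Chinese synonyms, an optional sourced definition,
#' free-form annotations (e.g. normal reference value, diagnostic cut-off)
#' and is_a parent links.
#'
#' @param iri Opaque identifier, unique within an ontology.
#' @param label_zh Chinese preferred label (non-empty).
#' @param labels_en Character vector of English names.
#' @param synonyms_zh Character vector of Chinese synonyms.
#' @param definition A [definition_record()] or `NULL`.
#' @param annotations Named character vector of annotation-property values.
#' @param parents Character vector of parent concept IRIs.
#' @return An object of class `cdmo_concept`.
#' @export
concept <- function(iri, label_zh, labels_en = character(),
                    synonyms_zh = character(), definition = NULL,
                    annotations = character(), parents = character()) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  stopifnot(is.character(label_zh), length(label_zh) == 1L, nzchar(label_zh))
  if (!is.null(definition) && !inherits(definition, "cdmo_definition")) {
    stop("`definition` must be a definition_record() or NULL", call. = FALSE)
  }
  parents <- unique(as.character(parents))
  if (iri %in% parents) {
    stop("concept '", iri, "' lists itself as a parent", call. = FALSE)
  }
  structure(
    list(iri = iri, label_zh = label_zh,
         labels_en = as.character(labels_en),
         synonyms_zh = as.character(synonyms_zh),
         definition = definition,
         annotations = annotations,
         parents = parents),
    class = "cdmo_concept"
  )
}

#' Create a property definition
#'
#' Object and annotation properties, optionally arranged in their own
#' hierarchy (e.g. "has common complications" under "has complication"),
#' with declared domain and range concept IRIs for object properties.
#'
#' @param name_zh Chinese property name (the key under which it is stored).
#' @param name_en English property name.
#' @param kind `"object"` or `"annotation"`.
#' @param parent Name of the parent property of the same kind, or `NULL`.
#' @param domain,range Character vectors of concept IRIs (object properties).
#' @return An object of class `cdmo_property`.
#' @export
property_def <- function(name_zh, name_en = "", kind = c("object", "annotation"),
                         parent = NULL, domain = character(),
                         range = character()) {
  kind <- match.arg(kind)
  stopifnot(is.character(name_zh), length(name_zh) == 1L, nzchar(name_zh))
  structure(
    list(name_zh = name_zh, name_en = name_en, kind = kind,
         parent = parent, domain = as.character(domain),
         range = as.character(range)),
    class = "cdmo_property"
  )
}

#' Assemble an ontology graph
#'
#' The terminological component (TBox): concepts keyed by IRI, properties
#' keyed by name, and the declared top-level roots. The union of all parent
#' links (the is_a relation) must be acyclic, every parent IRI must resolve,
#' and roots must have no parents; violations are errors.
#'
#' @param concepts List of [concept()] objects (names are taken from IRIs).
#' @param properties List of [property_def()] objects.
#' @param roots Character vector of root IRIs.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `cdmo_ontology`.
#' @export
ontology <- function(concepts = list(), properties = list(),
                     roots = character(), validate = TRUE) {
  if (length(concepts)) {
    iris <- vapply(concepts, function(x) x$iri, character(1))
    if (anyDuplicated(iris)) {
      stop("duplicate concept IRIs: ",
           paste(unique(iris[duplicated(iris)]), collapse = ", "),
           call. = FALSE)
    }
    names(concepts) <- iris
  }
  if (length(properties)) {
    names(properties) <- vapply(properties, function(x) x$name_zh, character(1))
  }
  g <- structure(
    list(concepts = concepts, properties = properties,
         roots = as.character(roots)),
    class = "cdmo_ontology"
  )
  if (validate) validate_ontology(g)
  g
}

#' Validate ontology invariants
#'
#' Errors on the first violated invariant: unresolved parent IRIs, roots with
#' parents, a cyclic is_a relation (the error names one cycle), or a property
#' parent of the wrong kind.
#'
#' @param graph A `cdmo_ontology`.
#' @return `graph`, invisibly.
#' @export
validate_ontology <- function(graph) {
  stopifnot(inherits(graph, "cdmo_ontology"))
  iris <- names(graph$concepts)
  for (con in graph$concepts) {
    bad <- setdiff(con$parents, iris)
    if (length(bad)) {
      stop("concept '", con$iri, "' has unresolved parent(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad_roots <- setdiff(graph$roots, iris)
  if (length(bad_roots)) {
    stop("root IRI(s) not in ontology: ", paste(bad_roots, collapse = ", "),
         call. = FALSE)
  }
  for (r in graph$roots) {
    if (length(graph$concepts[[r]]$parents)) {
      stop("root '", r, "' has parents", call. = FALSE)
    }
  }
  cyc <- find_isa_cycles(graph)
  if (length(cyc)) {
    stop("is_a relation is cyclic, e.g.: ",
         paste(cyc[[1]], collapse = " -> "), call. = FALSE)
  }
  for (p in graph$properties) {
    if (!is.null(p$parent)) {
      pp <- graph$properties[[p$parent]]
      if (is.null(pp)) {
        stop("property '", p$name_zh, "' has unresolved parent '",
             p$parent, "'", call. = FALSE)
      }
      if (pp$kind != p$kind) {
        stop("property '", p$name_zh, "' has parent of different kind",
             call. = FALSE)
      }
    }
  }
  invisible(graph)
}

# Tarjan-free cycle finder: iterative DFS colouring; returns a list of cycles
# (each a character vector of IRIs closing back on its first element).
find_isa_cycles <- function(graph) {
  iris <- names(graph$concepts)
  state <- stats::setNames(rep(0L, length(iris)), iris)  # 0 new, 1 open, 2 done
  cycles <- list()
  for (start in iris) {
    if (state[[start]] != 0L) next
    stack <- list(list(iri = start, next_parent = 1L))
    state[[start]] <- 1L
    path <- start
    while (length(stack)) {
      top <- stack[[length(stack)]]
      parents <- graph$concepts[[top$iri]]$parents
      if (top$next_parent > length(parents)) {
        state[[top$iri]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
        next
      }
      stack[[length(stack)]]$next_parent <- top$next_parent + 1L
      p <- parents[[top$next_parent]]
      if (state[[p]] == 1L) {
        i <- match(p, path)
        cycles[[length(cycles) + 1L]] <- c(path[i:length(path)], p)
      } else if (state[[p]] == 0L) {
        state[[p]] <- 1L
        stack[[length(stack) + 1L]] <- list(iri = p, next_parent = 1L)
        path <- c(path, p)
      }
    }
  }
  cycles
}

# -- queries ------------------------------------------------------------------

#' Subsumption test
#'
#' `TRUE` iff `b` is reachable from `a` via zero or more parent links: the
#' reflexive-transitive closure of is_a. Every concept subsumes itself.
#'
#' @param graph A `cdmo_ontology`.
#' @param a,b Concept IRIs present in `graph`.
#' @return Logical scalar.
#' @export
#' @examples
#' g <- make_micro_ontology()
#' is_subclass_of(g, iri_for_label("2型糖尿病"), iri_for_label("糖尿病"))
is_subclass_of <- function(graph, a, b) {
  if (is.null(graph$concepts[[a]])) stop("unknown IRI: ", a, call. = FALSE)
  if (is.null(graph$concepts[[b]])) stop("unknown IRI: ", b, call. = FALSE)
  if (a == b) return(TRUE)
  seen <- character()
  frontier <- a
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(x) graph$concepts[[x]]$parents),
                         use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (b %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' All ancestors of a concept (excluding itself)
#' @inheritParams is_subclass_of
#' @param iri Concept IRI.
#' @return Character vector of ancestor IRIs.
#' @export
ancestors <- function(graph, iri) {
  if (is.null(graph$concepts[[iri]])) stop("unknown IRI: ", iri, call. = FALSE)
  seen <- character()
  frontier <- iri
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(x) graph$concepts[[x]]$parents),
                         use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Add an is_a edge, atomically refusing cycles
#'
#' Adds `parent_iri` to the parents of `child_iri`. If the edge would make
#' the is_a relation cyclic the graph is returned unchanged and an error is
#' raised, so a failed mutation can never leave a cyclic graph behind.
#'
#' @inheritParams is_subclass_of
#' @param child_iri,parent_iri Concept IRIs.
#' @return The modified `cdmo_ontology`.
#' @export
add_parent <- function(graph, child_iri, parent_iri) {
  if (is.null(graph$concepts[[child_iri]])) {
    stop("unknown IRI: ", child_iri, call. = FALSE)
  }
  if (is.null(graph$concepts[[parent_iri]])) {
    stop("unknown IRI: ", parent_iri, call. = FALSE)
  }
  if (child_iri == parent_iri || is_subclass_of(graph, parent_iri, child_iri)) {
    stop("edge ", child_iri, " is_a ", parent_iri, " would create a cycle",
         call. = FALSE)
  }
  graph$concepts[[child_iri]]$parents <-
    unique(c(graph$concepts[[child_iri]]$parents, parent_iri))
  graph
}

#' Select one definition by source priority
#'
#' Given several candidate definitions for one concept, returns the one whose
#' source ranks highest in the order termonline > baidu > CHPO > MedDRA >
#' manual; ties within a source are broken by list order (first wins).
#'
#' @param candidates Non-empty list of [definition_record()] objects.
#' @return The winning `cdmo_definition`.
#' @export
select_definition <- function(candidates) {
  if (!length(candidates)) stop("no candidate definitions", call. = FALSE)
  stopifnot(all(vapply(candidates, inherits, logical(1), "cdmo_definition")))
  prio <- match(vapply(candidates, function(x) x$source, character(1)),
                definition_sources())
  candidates[[which.min(prio)]]
}

#' Stable IRI for a Chinese label
#'
#' Fixture concepts use opaque local names under a `cdmo:` prefix so labels
#' can be edited without breaking links: the local name is a 31-bit
#' polynomial hash of the label's UTF-8 bytes, printed as 8 hex digits.
#'
#' @param label_zh Chinese label string.
#' @return IRI string of the form `cdmo:xxxxxxxx`.
#' @export
iri_for_label <- function(label_zh) {
  vapply(label_zh, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 0
    for (b in bytes) {
      # exact in double precision: h*131 + b < 2^53
      h <- (h * 131 + b) %% 2147483647
    }
    sprintf("cdmo:%08x", h)
  }, character(1), USE.NAMES = FALSE)
}

# -- quality control ----------------------------------------------------------

#' Quality-control report for an ontology
#'
#' Automated checks standing in for ontology release tooling: is_a cycles,
#' orphan concepts (non-root concepts with no parent), missing definitions,
#' duplicate Chinese preferred labels (exact string equality), and — when an
#' ABox is supplied — object-property assertions whose subject or object type
#' is not subsumed by the property's declared domain or range.
#'
#' @param graph A `cdmo_ontology`.
#' @param abox Optional [knowledge_base()] whose assertions are checked
#'   against the property declarations of `graph`.
#' @return An object of class `cdmo_qc_report` with fields `cycles`,
#'   `orphans`, `missing_definitions`, `duplicate_labels`,
#'   `domain_range_violations`. An empty report means all checks pass; see
#'   [qc_clean()].
#' @export
qc_report <- function(graph, abox = NULL) {
  stopifnot(inherits(graph, "cdmo_ontology"))
  cycles <- find_isa_cycles(graph)
  iris <- names(graph$concepts)
  orphans <- iris[vapply(graph$concepts,
                         function(c) length(c$parents) == 0L, logical(1))]
  orphans <- setdiff(orphans, graph$roots)
  missing_def <- iris[vapply(graph$concepts,
                             function(c) is.null(c$definition), logical(1))]
  labels <- vapply(graph$concepts, function(c) c$label_zh, character(1))
  dup <- labels[duplicated(labels)]
  duplicate_labels <- lapply(unique(dup), function(l) {
    list(label = l, iris = unname(iris[labels == l]))
  })
  violations <- list()
  if (!is.null(abox)) {
    violations <- check_domain_range(graph, abox)
  }
  structure(
    list(cycles = cycles, orphans = unname(orphans),
         missing_definitions = unname(missing_def),
         duplicate_labels = duplicate_labels,
         domain_range_violations = violations),
    class = "cdmo_qc_report"
  )
}

# A subject/object satisfies a declared domain/range if one of its asserted
# types is subsumed by at least one declared class. Undeclared properties and
# unrestricted (empty) domains/ranges are never violations.
check_domain_range <- function(graph, abox) {
  find_prop <- function(name) {
    for (p in graph$properties) {
      if (p$name_zh == name || identical(p$name_en, name)) return(p)
    }
    NULL
  }
  ok_under <- function(types, declared) {
    if (!length(declared)) return(TRUE)
    for (t in types) {
      if (is.null(graph$concepts[[t]])) next
      for (d in declared) {
        if (!is.null(graph$concepts[[d]]) && is_subclass_of(graph, t, d)) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  out <- list()
  oa <- abox$object_assertions
  if (nrow(oa)) {
    for (i in seq_len(nrow(oa))) {
      p <- find_prop(oa$property[i])
      if (is.null(p) || p$kind != "object") next
      subj_types <- abox$individuals[[oa$subject[i]]]
      obj_types <- abox$individuals[[oa$object[i]]]
      assertion <- sprintf("%s(%s, %s)", oa$property[i], oa$subject[i],
                           oa$object[i])
      if (!ok_under(subj_types, p$domain)) {
        out[[length(out) + 1L]] <- list(
          assertion = assertion, property = oa$property[i],
          reason = "subject type outside declared domain")
      }
      if (!ok_under(obj_types, p$range)) {
        out[[length(out) + 1L]] <- list(
          assertion = assertion, property = oa$property[i],
          reason = "object type outside declared range")
      }
    }
  }
  out
}

#' Does a QC report contain no findings?
#' @param report A `cdmo_qc_report`.
#' @return Logical scalar.
#' @export
qc_clean <- function(report) {
  stopifnot(inherits(report, "cdmo_qc_report"))
  all(vapply(unclass(report), length, integer(1)) == 0L)
}

#' @export
print.cdmo_ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d concepts, %d properties, %d roots>\n",
              length(x$concepts), length(x$properties), length(x$roots)))
  invisible(x)
}

#' @export
print.cdmo_qc_report <- function(x, ...) {
  cat("Ontology QC report\n")
  cat(sprintf("  cycles:                  %d\n", length(x$cycles)))
  cat(sprintf("  orphans:                 %d\n", length(x$orphans)))
  cat(sprintf("  missing definitions:     %d\n", length(x$missing_definitions)))
  cat(sprintf("  duplicate labels:        %d\n", length(x$duplicate_labels)))
  cat(sprintf("  domain/range violations: %d\n",
              length(x$domain_range_violations)))
  cat(if (qc_clean(x)) "  all checks pass\n" else "  findings present\n")
  invisible(x)
}

#' Find a concept IRI by label
#'
#' Chinese lookups are exact and case-sensitive; English lookups are
#' case-insensitive and also search synonyms/alternative names.
#'
#' @inheritParams is_subclass_of
#' @param label Label string.
#' @param lang `"zh"` or `"en"`.
#' @return Character vector of matching IRIs (possibly empty).
#' @export
find_by_label <- function(graph, label, lang = c("zh", "en")) {
  lang <- match.arg(lang)
  hit <- vapply(graph$concepts, function(c) {
    if (lang == "zh") {
      label == c$label_zh || label %in% c$synonyms_zh
    } else {
      tolower(label) %in% tolower(c$labels_en)
    }
  }, logical(1))
  unname(names(graph$concepts)[hit])
}
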