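# Cross-lingual mapping: name-based candidate search against an English
# target ontology's lexicon, and automatic is_a hierarchy induction from
# established mappings (subsumption transfer with cycle/conflict guards).

#' Normalize an English concept name for matching
#'
#' Lowercases, removes SNOMED-style parenthesized semantic-tag suffixes such
#' as "(disorder)", strips punctuation, collapses whitespace and (by
#' default) sorts tokens so that word-order variants such as "hyperosmolar
#' hyperglycemic state" and "hyperglycemic hyperosmolar state" collide on
#' one key. Idempotent.
#'
#' @param name Character vector of names.
#' @param sort_tokens Sort tokens alphabetically (default `TRUE`); set
#'   `FALSE` for an exact-order key.
#' @return Character vector of normalized keys.
#' @export
#' @examples
#' normalize_name("Hyperosmolar hyperglycemic state")
#' normalize_name("hyperglycemic hyperosmolar state")
normalize_name <- function(name, sort_tokens = TRUE) {
  vapply(name, function(x) {
    x <- tolower(x)
    x <- gsub("\\([^)]*\\)", " ", x)          # "(disorder)" etc.
    x <- gsub("[^a-z0-9]+", " ", x)           # punctuation -> space
    toks <- strsplit(trimws(x), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (sort_tokens) toks <- utf8_sort(toks)
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a lexical index over a target ontology
#'
#' Every English label and synonym of every target class is indexed under
#' both its exact lowercased form and its [normalize_name()] key; colliding
#' names accumulate id sets.
#'
#' @param target A `cdmo_ontology` whose `labels_en` carry the target
#'   vocabulary.
#' @param sort_tokens Passed to [normalize_name()].
#' @return An object of class `cdmo_target_lexicon` with fields `exact`
#'   (map lowercased label -> ids), `normalized` (map key -> ids) and
#'   `graph` (the target ontology).
#' @export
build_lexical_index <- function(target, sort_tokens = TRUE) {
  stopifnot(inherits(target, "cdmo_ontology"))
  exact <- new.env(parent = emptyenv())
  norm <- new.env(parent = emptyenv())
  for (con in target$concepts) {
    names_en <- c(con$labels_en, con$synonyms_zh[grepl("^[ -~]+$", con$synonyms_zh)])
    for (nm in names_en) {
      k1 <- tolower(nm)
      exact[[k1]] <- unique(c(exact[[k1]], con$iri))
      k2 <- normalize_name(nm, sort_tokens = sort_tokens)
      if (nzchar(k2)) norm[[k2]] <- unique(c(norm[[k2]], con$iri))
    }
  }
  structure(list(exact = exact, normalized = norm, graph = target,
                 sort_tokens = sort_tokens),
            class = "cdmo_target_lexicon")
}

#' Propose cross-lingual mappings for one concept
#'
#' For each of the concept's English names: an exact (case-insensitive)
#' label hit yields a mapping with `match_type` "exact"; otherwise a
#' normalized-key hit yields "normalized"; no hit yields nothing. All hits
#' are returned, exact before normalized, then sorted by target id. A
#' concept with no English names yields an empty set and a "needs
#' translation" message (the manual translation step).
#'
#' @param con A [concept()] with English names.
#' @param lexicon A [build_lexical_index()] result.
#' @param target_ontology Name recorded on the mapping records (e.g.
#'   `"SNOMEDCT"`).
#' @return A mapping `data.frame` (see [mapping_records()]).
#' @export
propose_mappings <- function(con, lexicon, target_ontology = "TARGET") {
  stopifnot(inherits(lexicon, "cdmo_target_lexicon"))
  if (!length(con$labels_en)) {
    message("needs translation: concept ", con$iri, " (", con$label_zh,
            ") has no English names")
    return(mapping_records())
  }
  exact_ids <- character()
  norm_ids <- character()
  for (nm in con$labels_en) {
    hit <- lexicon$exact[[tolower(nm)]]
    if (!is.null(hit)) {
      exact_ids <- c(exact_ids, hit)
    } else {
      key <- normalize_name(nm, sort_tokens = lexicon$sort_tokens)
      hit <- lexicon$normalized[[key]]
      if (!is.null(hit)) norm_ids <- c(norm_ids, hit)
    }
  }
  exact_ids <- utf8_sort(unique(exact_ids))
  norm_ids <- utf8_sort(setdiff(unique(norm_ids), exact_ids))
  mapping_records(
    source_iri = rep(con$iri, length(exact_ids) + length(norm_ids)),
    target_ontology = target_ontology,
    target_id = c(exact_ids, norm_ids),
    match_type = c(rep("exact", length(exact_ids)),
                   rep("normalized", length(norm_ids)))
  )
}

#' Construct a mapping-record table
#'
#' Cross-lingual links from source concepts to target-ontology classes.
#' `match_type` is one of exact, normalized, manual; `similarity`, when
#' present, is carried as metadata only — no automatic acceptance threshold
#' is applied to it (lexical similarity scores are known to be unreliable:
#' a wrong match can score above 0.93).
#'
#' @param source_iri,target_ontology,target_id,match_type,similarity Column
#'   vectors (recycled to common length).
#' @return `data.frame` of class `cdmo_mappings`.
#' @export
mapping_records <- function(source_iri = character(),
                            target_ontology = character(),
                            target_id = character(),
                            match_type = character(),
                            similarity = NA_real_) {
  n <- length(source_iri)
  if (n > 0L) {
    stopifnot(all(match_type %in% c("exact", "normalized", "manual")))
    if (!all(is.na(similarity))) {
      stopifnot(all(is.na(similarity) | (similarity >= 0 & similarity <= 1)))
    }
  }
  out <- data.frame(
    source_iri = as.character(source_iri),
    target_ontology = rep_len(as.character(target_ontology), n),
    target_id = as.character(target_id),
    match_type = rep_len(as.character(match_type), n),
    similarity = rep_len(as.numeric(similarity), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cdmo_mappings", "data.frame")
  out
}

#' Induce is_a edges in the source ontology from mappings
#'
#' For every pair of source concepts mapped into the same target ontology,
#' if the target asserts that the first mapped class is a child of the
#' second (direct mode: an asserted parent link; transitive mode:
#' reachability), the corresponding source edge is proposed. Evidence is
#' never chained across two different target ontologies. Transitive-mode
#' proposals are transitively reduced against the combined (existing +
#' accepted) edge set. An edge that would make the source cyclic is returned
#' with status `rejected_cycle`; an edge whose reverse is already asserted
#' in the source (`parent` already below `child`) is `rejected_conflict`.
#' Accepted edges are applied to a working copy incrementally, so the result
#' is acyclic by construction.
#'
#' @param source A `cdmo_ontology` to extend.
#' @param mappings A `cdmo_mappings` table.
#' @param targets Named list of target `cdmo_ontology` graphs, keyed by
#'   target-ontology name.
#' @param mode `"transitive"` (default) or `"direct"`.
#' @param apply If `TRUE`, also return the extended source graph.
#' @return `data.frame` of class `cdmo_induced_edges` with columns
#'   `child_iri`, `parent_iri`, `target_ontology`, `child_target_id`,
#'   `parent_target_id`, `status`. With `apply = TRUE`, a list
#'   `list(edges, graph)`.
#' @export
induce_hierarchy <- function(source, mappings, targets,
                             mode = c("transitive", "direct"),
                             apply = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(source, "cdmo_ontology"))
  for (i in seq_len(nrow(mappings))) {
    tg <- targets[[mappings$target_ontology[i]]]
    if (is.null(tg)) {
      stop("no target graph for ontology '", mappings$target_ontology[i], "'",
           call. = FALSE)
    }
    if (is.null(tg$concepts[[mappings$target_id[i]]])) {
      stop("mapping ", mappings$source_iri[i], " -> ",
           mappings$target_ontology[i], ":", mappings$target_id[i],
           " does not resolve in the target graph", call. = FALSE)
    }
  }
  proposals <- list()
  for (onto in sort(unique(mappings$target_ontology))) {
    sub <- mappings[mappings$target_ontology == onto, , drop = FALSE]
    tg <- targets[[onto]]
    # deterministic pair order: sorted by child then parent source IRI
    o <- order(enc2utf8(sub$source_iri), enc2utf8(sub$target_id), method = "radix")
    sub <- sub[o, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      for (j in seq_len(nrow(sub))) {
        if (i == j) next
        c_iri <- sub$source_iri[i]; p_iri <- sub$source_iri[j]
        if (c_iri == p_iri) next
        c_tid <- sub$target_id[i]; p_tid <- sub$target_id[j]
        if (c_tid == p_tid) next
        below <- if (mode == "direct") {
          p_tid %in% tg$concepts[[c_tid]]$parents
        } else {
          is_subclass_of(tg, c_tid, p_tid)
        }
        if (below) {
          proposals[[length(proposals) + 1L]] <- list(
            child_iri = c_iri, parent_iri = p_iri, target_ontology = onto,
            child_target_id = c_tid, parent_target_id = p_tid)
        }
      }
    }
  }
  if (!length(proposals)) {
    edges <- induced_edge_table()
    return(if (apply) list(edges = edges, graph = source) else edges)
  }
  # dedupe (same source pair may be witnessed by several target pairs; keep
  # the first witness in deterministic order)
  key <- vapply(proposals, function(e) paste(e$child_iri, e$parent_iri),
                character(1))
  proposals <- proposals[!duplicated(key)]
  key <- key[!duplicated(key)]
  ord <- order(enc2utf8(key), method = "radix")
  proposals <- proposals[ord]

  if (mode == "transitive") {
    proposals <- transitive_reduce_proposals(source, proposals)
  }
  work <- source
  status <- character(length(proposals))
  for (k in seq_along(proposals)) {
    e <- proposals[[k]]
    if (is_subclass_of(source, e$parent_iri, e$child_iri)) {
      # the original source already asserts the reverse: a contradiction
      status[k] <- "rejected_conflict"
      next
    }
    if (is_subclass_of(work, e$parent_iri, e$child_iri)) {
      # reverse path introduced by previously accepted edges: cycle guard
      status[k] <- "rejected_cycle"
      next
    }
    work <- add_parent(work, e$child_iri, e$parent_iri)
    status[k] <- "accepted"
  }
  edges <- induced_edge_table(
    child_iri = vapply(proposals, `[[`, character(1), "child_iri"),
    parent_iri = vapply(proposals, `[[`, character(1), "parent_iri"),
    target_ontology = vapply(proposals, `[[`, character(1), "target_ontology"),
    child_target_id = vapply(proposals, `[[`, character(1), "child_target_id"),
    parent_target_id = vapply(proposals, `[[`, character(1), "parent_target_id"),
    status = status
  )
  stopifnot(length(find_isa_cycles(work)) == 0L)
  if (apply) list(edges = edges, graph = work) else edges
}

induced_edge_table <- function(child_iri = character(),
                               parent_iri = character(),
                               target_ontology = character(),
                               child_target_id = character(),
                               parent_target_id = character(),
                               status = character()) {
  out <- data.frame(child_iri = child_iri, parent_iri = parent_iri,
                    target_ontology = target_ontology,
                    child_target_id = child_target_id,
                    parent_target_id = parent_target_id,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("cdmo_induced_edges", "data.frame")
  out
}

# Drop a proposed edge (c, p) when p is reachable from c through a chain of
# length >= 2 over proposed + existing edges: keeps the applied source graph
# transitively minimal.
transitive_reduce_proposals <- function(source, proposals) {
  padj <- list()
  for (e in proposals) {
    padj[[e$child_iri]] <- unique(c(padj[[e$child_iri]], e$parent_iri))
  }
  reach_via_two <- function(child, parent) {
    # BFS from child over combined parents, excluding the direct hop
    step <- function(x) unique(c(padj[[x]],
                                 if (!is.null(source$concepts[[x]]))
                                   source$concepts[[x]]$parents))
    first <- setdiff(step(child), parent)
    seen <- character()
    frontier <- first
    while (length(frontier)) {
      if (parent %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, step))), seen)
    }
    FALSE
  }
  keep <- vapply(proposals, function(e) {
    !reach_via_two(e$child_iri, e$parent_iri)
  }, logical(1))
  proposals[keep]
}

# -- mapping CSV --------------------------------------------------------------

#' Write mapping records to CSV
#'
#' Columns `source_iri`, `target_ontology`, `target_id`, `match_type`,
#' `similarity`; [read_mappings()] restores an identical table.
#'
#' @param records A `cdmo_mappings` table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mappings <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read mapping records from CSV
#' @param path File path.
#' @return `data.frame` of class `cdmo_mappings`.
#' @export
read_mappings <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                         colClasses = c(source_iri = "character",
                                        target_ontology = "character",
                                        target_id = "character",
                                        match_type = "character",
                                        similarity = "numeric"))
  need <- c("source_iri", "target_ontology", "target_id", "match_type",
            "similarity")
  if (!all(need %in% names(raw))) {
    stop("mapping CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!raw$match_type %in% c("exact", "normalized", "manual"))
  if (length(bad)) {
    stop("malformed mapping row at line ", bad[1] + 1L,
         ": bad match_type '", raw$match_type[bad[1]], "'", call. = FALSE)
  }
  mapping_records(raw$source_iri, raw$target_ontology, raw$target_id,
                  raw$match_type, raw$similarity)
}

#' Per-target-ontology mapping counts
#'
#' The tabular mapping summary: one row per target ontology with its number
#' of mapping records, sorted by decreasing count then name.
#'
#' @param records A `cdmo_mappings` table.
#' @return `data.frame` with columns `target_ontology`, `n`.
#' @export
mapping_summary <- function(records) {
  tab <- table(records$target_ontology)
  out <- data.frame(target_ontology = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n, out$target_ontology), , drop = FALSE]
}

#' Flag concepts mapped into both a substance and a procedure branch
#'
#' Chinese clinical text often conflates an analyte (creatinine) with the
#' laboratory procedure measuring it (creatinine measurement). A source
#' concept simultaneously mapped under a target substance branch and a
#' target procedure branch is reported as a warning-level QC finding, never
#' auto-resolved.
#'
#' @param mappings A `cdmo_mappings` table.
#' @param targets Named list of target graphs.
#' @param substance_roots,procedure_roots Named lists: for each target
#'   ontology name, the IRI of its substance / procedure branch root.
#' @return Character vector of flagged source IRIs.
#' @export
flag_substance_measurement <- function(mappings, targets,
                                       substance_roots, procedure_roots) {
  flagged <- character()
  for (src in unique(mappings$source_iri)) {
    rows <- mappings[mappings$source_iri == src, , drop = FALSE]
    in_sub <- FALSE; in_proc <- FALSE
    for (i in seq_len(nrow(rows))) {
      onto <- rows$target_ontology[i]
      tg <- targets[[onto]]
      sr <- substance_roots[[onto]]; pr <- procedure_roots[[onto]]
      if (is.null(tg) || is.null(tg$concepts[[rows$target_id[i]]])) next
      if (!is.null(sr) && is_subclass_of(tg, rows$target_id[i], sr)) in_sub <- TRUE
      if (!is.null(pr) && is_subclass_of(tg, rows$target_id[i], pr)) in_proc <- TRUE
    }
    if (in_sub && in_proc) flagged <- c(flagged, src)
  }
  flagged
}
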