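# SWRL-style positive Horn rules over a TBox+ABox knowledge base:
# parser for the plain-text rule dialect, subsumption-aware class matching,
# numeric comparison builtins, and a set-at-a-time forward-chaining fixpoint
# with per-derivation explanations.

# -- terms and atoms ----------------------------------------------------------

rule_term <- function(x) {
  x <- trimws(x)
  # strip typographic quote characters that creep into printed rule text
  x <- gsub("[‘’“”']", "", x)
  if (startsWith(x, "?")) {
    nm <- substring(x, 2L)
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", nm)) {
      stop("malformed variable '", x, "'", call. = FALSE)
    }
    return(list(type = "var", name = nm))
  }
  if (grepl("^[-+]?[0-9]+(\\.[0-9]+)?$", x)) {
    return(list(type = "lit", value = as.numeric(x)))
  }
  if (!nzchar(x)) stop("empty atom argument", call. = FALSE)
  list(type = "ind", name = x)
}

parse_atom <- function(text, offset = NA_integer_) {
  text <- trimws(text)
  m <- regexec("^([^()]+)\\(([^()]*)\\)$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 3L) {
    stop("malformed atom at offset ", offset, ": '", text, "'", call. = FALSE)
  }
  pred <- trimws(parts[2])
  pred <- gsub("[‘’“”']", "", pred)  # printed-text artifacts
  builtin <- grepl("^swrlb:", pred)
  if (builtin) {
    pred <- sub("^swrlb:", "", pred)
  } else {
    pred <- sub("^(CDMO|cdmo):", "", pred)
  }
  args <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
  args <- lapply(args, rule_term)
  kind <- if (builtin) {
    if (length(args) < 2L) {
      stop("builtin atom '", pred, "' needs >= 2 arguments", call. = FALSE)
    }
    "builtin"
  } else if (length(args) == 1L) {
    "class"
  } else if (length(args) == 2L) {
    "property"
  } else {
    stop("atom '", pred, "' has ", length(args),
         " arguments; expected 1 (class) or 2 (property)", call. = FALSE)
  }
  list(kind = kind, predicate = pred, args = args)
}

atom_vars <- function(atom) {
  unlist(lapply(atom$args, function(t) if (t$type == "var") t$name),
         use.names = FALSE)
}

#' Parse one rule from the plain-text dialect
#'
#' Dialect: `name: atom ^ atom ^ ... -> atom ^ atom`, atoms written
#' `pred(arg, ...)`, variables `?x`, numeric literals bare, builtins
#' prefixed `swrlb:`, optional `CDMO:`/`cdmo:` prefixes stripped. Both the
#' ASCII arrow `->` and the typeset em-dash arrow are accepted, and stray
#' typographic quotes in predicate names are removed, so rule text copied
#' from print renders parses as written. Whitespace-insensitive.
#'
#' Every consequent variable must be bound in the antecedent and the
#' consequent may not contain builtins (positive Horn rules only).
#'
#' @param text Rule string.
#' @param comment Natural-language explanation kept with the rule.
#' @return An object of class `cdmo_rule` with fields `name`, `antecedent`,
#'   `consequent`, `comment`.
#' @export
#' @examples
#' parse_rule("r: p(?x) -> q(?x)")
parse_rule <- function(text, comment = "") {
  raw <- paste(text, collapse = " ")
  # the typeset arrow is an em dash (or minus variants) followed by '>'
  norm <- gsub("[—–−]\\s*>", "->", raw)
  m <- regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", norm)
  parts <- regmatches(norm, m)[[1]]
  if (length(parts) != 3L) {
    stop("rule must start with 'name:' — got '",
         substr(norm, 1, 40), "'", call. = FALSE)
  }
  name <- parts[2]
  body <- parts[3]
  halves <- strsplit(body, "->", fixed = TRUE)[[1]]
  if (length(halves) != 2L) {
    stop("rule '", name, "' must contain exactly one '->'", call. = FALSE)
  }
  split_atoms <- function(s, base_offset) {
    pieces <- strsplit(s, "^", fixed = TRUE)[[1]]
    off <- base_offset
    out <- list()
    for (p in pieces) {
      out[[length(out) + 1L]] <- parse_atom(p, offset = off)
      off <- off + nchar(p) + 1L
    }
    out
  }
  antecedent <- split_atoms(halves[1], 1L)
  consequent <- split_atoms(halves[2], nchar(halves[1]) + 3L)
  ante_vars <- unique(unlist(lapply(antecedent, atom_vars)))
  for (atom in consequent) {
    if (atom$kind == "builtin") {
      stop("rule '", name, "': builtin atom '", atom$predicate,
           "' not allowed in consequent", call. = FALSE)
    }
    unbound <- setdiff(atom_vars(atom), ante_vars)
    if (length(unbound)) {
      stop("rule '", name, "': consequent variable ?", unbound[1],
           " is not bound in the antecedent", call. = FALSE)
    }
  }
  structure(list(name = name, antecedent = antecedent,
                 consequent = consequent, comment = comment),
            class = "cdmo_rule")
}

#' Parse a rule file
#'
#' Plain text, one rule per block (blocks separated by blank lines); `#`
#' lines immediately above a rule are attached as its natural-language
#' comment; a rule may wrap over several lines.
#'
#' @param path File path.
#' @return Named list of `cdmo_rule` objects.
#' @export
parse_rules <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rules <- list()
  comment <- character()
  block <- character()
  flush <- function() {
    if (length(block)) {
      r <- parse_rule(paste(block, collapse = " "),
                      comment = paste(comment, collapse = " "))
      if (r$name %in% names(rules)) {
        stop("duplicate rule name '", r$name, "'", call. = FALSE)
      }
      rules[[r$name]] <<- r
    }
    comment <<- character()
    block <<- character()
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) {
      flush()
    } else if (startsWith(t, "#")) {
      comment <- c(comment, sub("^#\\s*", "", t))
    } else {
      block <- c(block, t)
    }
  }
  flush()
  rules
}

#' @export
print.cdmo_rule <- function(x, ...) {
  fmt <- function(a) {
    args <- vapply(a$args, function(t) {
      switch(t$type, var = paste0("?", t$name), ind = t$name,
             lit = format(t$value))
    }, character(1))
    pfx <- if (a$kind == "builtin") "swrlb:" else ""
    sprintf("%s%s(%s)", pfx, a$predicate, paste(args, collapse = ", "))
  }
  cat(sprintf("%s: %s -> %s\n", x$name,
              paste(vapply(x$antecedent, fmt, character(1)), collapse = " ^ "),
              paste(vapply(x$consequent, fmt, character(1)), collapse = " ^ ")))
  if (nzchar(x$comment)) cat("  # ", x$comment, "\n", sep = "")
  invisible(x)
}

# -- knowledge base -----------------------------------------------------------

#' Assemble a knowledge base (TBox + ABox)
#'
#' Individuals carry sets of asserted type IRIs; object assertions are
#' (property, subject, object) triples over individual names; data
#' assertions are (property, subject, numeric value, unit string). Asserted
#' types must resolve in the TBox and values must be finite.
#'
#' @param tbox A `cdmo_ontology`.
#' @param individuals Named list: individual name -> character vector of
#'   type IRIs (labels are resolved through the TBox).
#' @param object_assertions `data.frame` with columns `property`, `subject`,
#'   `object` (or a list of length-3 vectors).
#' @param data_assertions `data.frame` with columns `property`, `subject`,
#'   `value`, `unit` (or a list of length-3/4 vectors; unit defaults `""`).
#' @return An object of class `cdmo_kb`.
#' @export
knowledge_base <- function(tbox, individuals = list(),
                           object_assertions = NULL, data_assertions = NULL) {
  stopifnot(inherits(tbox, "cdmo_ontology"))
  oa <- as_assertion_df(object_assertions, c("property", "subject", "object"))
  da <- as_assertion_df(data_assertions, c("property", "subject", "value", "unit"))
  da$value <- as.numeric(da$value)
  if (nrow(da) && any(!is.finite(da$value))) {
    stop("data assertion values must be finite numbers", call. = FALSE)
  }
  individuals <- lapply(individuals, function(types) {
    vapply(types, function(t) resolve_class(tbox, t), character(1),
           USE.NAMES = FALSE)
  })
  kb <- structure(list(tbox = tbox, individuals = individuals,
                       object_assertions = oa, data_assertions = da),
                  class = "cdmo_kb")
  for (nm in c(oa$subject, oa$object, da$subject)) {
    if (is.null(kb$individuals[[nm]])) {
      # assertion subjects/objects need not be typed, but must exist
      kb$individuals[[nm]] <- character()
    }
  }
  kb
}

as_assertion_df <- function(x, cols) {
  if (is.null(x)) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                         cols), stringsAsFactors = FALSE)
    return(out)
  }
  if (is.data.frame(x)) {
    if ("unit" %in% cols && !"unit" %in% names(x)) x$unit <- ""
    missing <- setdiff(cols, names(x))
    if (length(missing)) {
      stop("assertion table missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(x[cols])
  }
  rows <- lapply(x, function(r) {
    r <- as.list(r)
    if (length(r) == length(cols) - 1L && "unit" %in% cols) r <- c(r, "")
    stats::setNames(r, cols)
  })
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

# Resolve a class reference (IRI, English name, or Chinese label) to an IRI.
resolve_class <- function(tbox, ref) {
  if (!is.null(tbox$concepts[[ref]])) return(ref)
  hit <- find_by_label(tbox, ref, lang = "en")
  if (!length(hit)) {
    # rule predicates use underscore_case English names
    hit <- find_by_label(tbox, gsub("_", " ", ref), lang = "en")
  }
  if (!length(hit)) hit <- find_by_label(tbox, ref, lang = "zh")
  if (length(hit) != 1L) {
    stop("cannot resolve class reference '", ref, "' (",
         length(hit), " hits)", call. = FALSE)
  }
  hit
}

# -- matching -----------------------------------------------------------------

#' Enumerate bindings for a class atom
#'
#' A variable binds to every individual whose asserted type is the atom's
#' class or any subclass of it — subsumption-aware matching via
#' [is_subclass_of()], so an individual typed with a subtype also satisfies
#' the supertype atom.
#'
#' @param kb A `cdmo_kb`.
#' @param atom A class atom.
#' @param binding Named list of existing variable bindings (default none).
#' @return `data.frame` of extended bindings, one column per variable.
#' @export
match_class_atom <- function(kb, atom, binding = list()) {
  stopifnot(atom$kind == "class")
  ext <- atom_extension(kb, atom)
  merge_bindings(binding_df(binding), ext)
}

binding_df <- function(binding) {
  if (is.data.frame(binding)) return(binding)
  if (!length(binding)) {
    return(structure(data.frame(.dummy = 1)[, 0, drop = FALSE],
                     row.names = 1L))
  }
  as.data.frame(binding, stringsAsFactors = FALSE)
}

class_members <- function(kb, class_iri) {
  if (is.null(kb$tbox$concepts[[class_iri]])) {
    stop("unknown class IRI '", class_iri, "' in class atom", call. = FALSE)
  }
  names(kb$individuals)[vapply(kb$individuals, function(types) {
    any(vapply(types, function(t) is_subclass_of(kb$tbox, t, class_iri),
               logical(1)))
  }, logical(1))]
}

# Extension of a non-builtin atom as a data.frame keyed by its variables.
# Data-property atoms bind value variables to numerics and carry the unit in
# a shadow column `.unit_<var>`.
atom_extension <- function(kb, atom, expand_subproperties = FALSE) {
  if (atom$kind == "class") {
    iri <- resolve_class(kb$tbox, atom$predicate)
    members <- class_members(kb, iri)
    arg <- atom$args[[1]]
    if (arg$type == "var") {
      out <- data.frame(v = members, stringsAsFactors = FALSE)
      names(out) <- arg$name
      return(out)
    }
    n <- if (arg$name %in% members) 1L else 0L
    return(structure(data.frame(.dummy = 1)[seq_len(n), 0, drop = FALSE]))
  }
  stopifnot(atom$kind == "property")
  da <- kb$data_assertions
  is_data <- atom$predicate %in% da$property
  if (is_data) {
    rows <- da[da$property == atom$predicate, , drop = FALSE]
    return(pair_extension(atom, rows$subject, rows$value, rows$unit))
  }
  preds <- atom$predicate
  if (expand_subproperties) {
    preds <- c(preds, descendant_properties(kb$tbox, atom$predicate))
  }
  oa <- kb$object_assertions
  rows <- oa[oa$property %in% preds, , drop = FALSE]
  pair_extension(atom, rows$subject, rows$object, NULL)
}

descendant_properties <- function(tbox, name) {
  # property referenced by English name or zh key; descend the sub-property
  # hierarchy and return all alias names of all descendants
  all_names <- function(p) c(p$name_zh, if (nzchar(p$name_en)) p$name_en)
  target_keys <- character()
  for (p in tbox$properties) {
    if (name %in% all_names(p)) target_keys <- c(target_keys, p$name_zh)
  }
  if (!length(target_keys)) return(character())
  out <- character()
  repeat {
    kids <- vapply(tbox$properties, function(p) {
      !is.null(p$parent) && p$parent %in% target_keys &&
        !(p$name_zh %in% c(target_keys, out))
    }, logical(1))
    if (!any(kids)) break
    new_keys <- vapply(tbox$properties[kids], `[[`, character(1), "name_zh")
    out <- c(out, new_keys)
    target_keys <- c(target_keys, new_keys)
  }
  unlist(lapply(tbox$properties[out], all_names), use.names = FALSE)
}

pair_extension <- function(atom, first, second, units) {
  a1 <- atom$args[[1]]; a2 <- atom$args[[2]]
  df <- data.frame(.f = first, stringsAsFactors = FALSE)
  df$.s <- second
  if (!is.null(units)) df$.u <- units
  # constant positions filter rows; variable positions become columns
  keep <- rep(TRUE, nrow(df))
  same_var <- a1$type == "var" && a2$type == "var" && a1$name == a2$name
  if (same_var) keep <- keep & df$.f == df$.s
  cols <- list()
  if (a1$type == "var") {
    cols[[a1$name]] <- df$.f
  } else {
    keep <- keep & df$.f == a1$name
  }
  if (a2$type == "var" && !same_var) {
    cols[[a2$name]] <- df$.s
    if (!is.null(units)) cols[[paste0(".unit_", a2$name)]] <- df$.u
  } else if (a2$type == "lit") {
    keep <- keep & df$.s == a2$value
  } else if (a2$type == "ind") {
    keep <- keep & df$.s == a2$name
  }
  if (!length(cols)) {
    return(structure(data.frame(.dummy = 1)[seq_len(sum(keep)), 0,
                                            drop = FALSE]))
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  unique(out[keep, , drop = FALSE])
}

merge_bindings <- function(b, ext) {
  if (ncol(b) == 0L) {
    if (nrow(b) == 0L) return(ext[0, , drop = FALSE])
    return(ext)
  }
  if (ncol(ext) == 0L) {
    return(b[rep(seq_len(nrow(b)), length.out = nrow(b) * (nrow(ext) > 0)), ,
             drop = FALSE])
  }
  shared <- intersect(names(b), names(ext))
  if (!length(shared)) {
    if (nrow(b) == 0L || nrow(ext) == 0L) {
      out <- cbind(b[0, , drop = FALSE], ext[0, , drop = FALSE])
      return(out)
    }
    return(merge(b, ext, by = NULL))
  }
  merge(b, ext, by = shared)
}

#' Evaluate a comparison builtin
#'
#' Supported: greaterThanOrEqual, greaterThan, lessThanOrEqual, lessThan,
#' equal, notEqual, compared exactly on the stored numeric values.
#' Builtins never bind variables: unbound arguments are an error, as are
#' unknown builtin names. Two bound values carrying different non-empty
#' units are an error (no unit conversion).
#'
#' @param predicate Builtin name without the `swrlb:` prefix.
#' @param args Numeric vector of bound argument values (length 2).
#' @param units Optional character vector of units parallel to `args`.
#' @return Logical scalar.
#' @export
eval_builtin <- function(predicate, args, units = NULL) {
  if (length(args) != 2L || anyNA(args)) {
    stop("builtin '", predicate,
         "' requires two bound numeric arguments", call. = FALSE)
  }
  if (!is.null(units)) {
    u <- units[nzchar(units)]
    if (length(unique(u)) > 1L) {
      stop("builtin '", predicate, "' compares values with different units: ",
           paste(unique(u), collapse = " vs "), call. = FALSE)
    }
  }
  a <- as.numeric(args[1]); b <- as.numeric(args[2])
  switch(predicate,
         greaterThanOrEqual = a >= b,
         greaterThan = a > b,
         lessThanOrEqual = a <= b,
         lessThan = a < b,
         equal = a == b,
         notEqual = a != b,
         stop("unknown builtin 'swrlb:", predicate, "'", call. = FALSE))
}

rule_bindings <- function(kb, rule, expand_subproperties = FALSE) {
  b <- binding_df(list())
  for (atom in rule$antecedent) {
    if (atom$kind == "builtin") {
      if (nrow(b) == 0L) next
      keep <- vapply(seq_len(nrow(b)), function(i) {
        vals <- numeric(0); units <- character(0)
        for (t in atom$args) {
          if (t$type == "var") {
            if (!t$name %in% names(b)) {
              stop("builtin '", atom$predicate, "' argument ?", t$name,
                   " is unbound (builtins never bind)", call. = FALSE)
            }
            vals <- c(vals, as.numeric(b[[t$name]][i]))
            ucol <- paste0(".unit_", t$name)
            units <- c(units, if (ucol %in% names(b)) b[[ucol]][i] else "")
          } else if (t$type == "lit") {
            vals <- c(vals, t$value)
            units <- c(units, "")
          } else {
            stop("builtin '", atom$predicate,
                 "' takes numeric arguments only", call. = FALSE)
          }
        }
        eval_builtin(atom$predicate, vals, units)
      }, logical(1))
      b <- b[keep, , drop = FALSE]
    } else {
      ext <- atom_extension(kb, atom, expand_subproperties)
      b <- merge_bindings(b, ext)
    }
    if (nrow(b) == 0L && ncol(b) > 0L) {
      # no satisfying bindings; later atoms cannot resurrect any
      return(b)
    }
  }
  unique(b)
}

assertion_key <- function(a) {
  if (a$kind == "type") paste("type", a$individual, a$class, sep = "|")
  else paste("object", a$property, a$subject, a$object, sep = "|")
}

instantiate_consequent <- function(kb, atom, row) {
  val <- function(t) {
    if (t$type == "var") as.character(row[[t$name]])
    else if (t$type == "ind") t$name
    else as.character(t$value)
  }
  if (atom$kind == "class") {
    list(kind = "type", individual = val(atom$args[[1]]),
         class = resolve_class(kb$tbox, atom$predicate))
  } else {
    list(kind = "object", property = atom$predicate,
         subject = val(atom$args[[1]]), object = val(atom$args[[2]]))
  }
}

#' Forward-chain a rule set to fixpoint
#'
#' Set-at-a-time evaluation: each pass computes every satisfying binding of
#' every rule against the current knowledge base, asserts the instantiated
#' consequents, and repeats until a pass derives nothing new. Derived type
#' and object assertions can trigger further rules. The result is
#' order-independent (any permutation of rules or assertions yields the same
#' closure) and idempotent (re-running on the closure derives nothing).
#'
#' @param kb A `cdmo_kb`.
#' @param rules List of `cdmo_rule` (or a single rule).
#' @param max_iterations Pass limit guarding against pathological rule sets;
#'   exceeding it is an error reporting the last-added assertions.
#' @param expand_subproperties Match object-property atoms against asserted
#'   sub-properties too (default `FALSE`: leaf-property matching only).
#' @return An object of class `cdmo_inference`: `derived` (list of new
#'   assertions), `trace` (rule name, variable binding, derived assertion,
#'   rule comment — one entry per firing), `iterations`, and `kb` (the
#'   closure).
#' @export
forward_chain <- function(kb, rules, max_iterations = 100L,
                          expand_subproperties = FALSE) {
  stopifnot(inherits(kb, "cdmo_kb"))
  if (inherits(rules, "cdmo_rule")) rules <- list(rules)
  initial_keys <- kb_assertion_keys(kb)
  known <- new.env(parent = emptyenv())
  for (k in initial_keys) known[[k]] <- TRUE
  derived <- list()
  trace <- list()
  iterations <- 0L
  repeat {
    if (iterations >= max_iterations) {
      last <- vapply(utils::tail(derived, 3L), assertion_key, character(1))
      stop("forward chaining did not reach a fixpoint within ",
           max_iterations, " iterations; last added: ",
           paste(last, collapse = "; "), call. = FALSE)
    }
    iterations <- iterations + 1L
    added <- FALSE
    for (rule in rules) {
      b <- rule_bindings(kb, rule, expand_subproperties)
      if (nrow(b) == 0L) next
      vis <- names(b)[!startsWith(names(b), ".unit_")]
      for (i in seq_len(nrow(b))) {
        bind <- stats::setNames(
          lapply(vis, function(v) b[[v]][i]), vis)
        for (atom in rule$consequent) {
          a <- instantiate_consequent(kb, atom, b[i, , drop = FALSE])
          k <- assertion_key(a)
          if (is.null(known[[k]])) {
            known[[k]] <- TRUE
            derived[[length(derived) + 1L]] <- a
            if (a$kind == "type") {
              kb$individuals[[a$individual]] <-
                unique(c(kb$individuals[[a$individual]], a$class))
            } else {
              kb$object_assertions <- rbind(
                kb$object_assertions,
                data.frame(property = a$property, subject = a$subject,
                           object = a$object, stringsAsFactors = FALSE))
            }
            added <- TRUE
          }
          # record every firing that (re-)supports this assertion once per
          # (rule, binding, assertion)
          tkey <- paste(rule$name, k,
                        paste(vis, unlist(bind), collapse = ","), sep = "##")
          if (!k %in% initial_keys && is.null(known[[tkey]])) {
            known[[tkey]] <- TRUE
            trace[[length(trace) + 1L]] <- list(
              rule = rule$name, binding = bind, assertion = a,
              comment = rule$comment)
          }
        }
      }
    }
    if (!added) break
  }
  structure(list(derived = derived, trace = trace, iterations = iterations,
                 kb = kb),
            class = "cdmo_inference")
}

kb_assertion_keys <- function(kb) {
  keys <- character()
  for (nm in names(kb$individuals)) {
    for (t in kb$individuals[[nm]]) {
      keys <- c(keys, paste("type", nm, t, sep = "|"))
    }
  }
  oa <- kb$object_assertions
  if (nrow(oa)) {
    keys <- c(keys, paste("object", oa$property, oa$subject, oa$object,
                          sep = "|"))
  }
  keys
}

#' @export
print.cdmo_inference <- function(x, ...) {
  cat(sprintf("<inference: %d derived assertion(s) in %d pass(es)>\n",
              length(x$derived), x$iterations))
  for (a in x$derived) {
    if (a$kind == "type") {
      cat(sprintf("  %s rdf:type %s\n", a$individual, a$class))
    } else {
      cat(sprintf("  %s(%s, %s)\n", a$property, a$subject, a$object))
    }
  }
  invisible(x)
}

#' Was a given object assertion derived?
#'
#' @param result A `cdmo_inference`.
#' @param property,subject,object Assertion components; `object = NULL`
#'   matches any object.
#' @return Logical scalar.
#' @export
was_derived <- function(result, property, subject = NULL, object = NULL) {
  for (a in result$derived) {
    if (a$kind != "object") next
    if (a$property != property) next
    if (!is.null(subject) && a$subject != subject) next
    if (!is.null(object) && a$object != object) next
    return(TRUE)
  }
  FALSE
}

#' Explain a derived assertion
#'
#' Returns every trace entry supporting the assertion: the rule name, the
#' full variable binding of the firing, and the rule's natural-language
#' comment — the material a clinician-facing display would show next to a
#' recommendation.
#'
#' @param result A `cdmo_inference`.
#' @param assertion An assertion record as found in `result$derived`, or a
#'   list with fields (`kind = "object"`, `property`, `subject`, `object`)
#'   or (`kind = "type"`, `individual`, `class`).
#' @return List of trace entries.
#' @export
explain <- function(result, assertion) {
  stopifnot(inherits(result, "cdmo_inference"))
  key <- assertion_key(assertion)
  if (!key %in% vapply(result$derived, assertion_key, character(1))) {
    stop("assertion was not derived: ", key, call. = FALSE)
  }
  Filter(function(t) assertion_key(t$assertion) == key, result$trace)
}

# -- patient ABox JSON --------------------------------------------------------

#' Read a patient ABox from JSON
#'
#' Format: `{"individuals": [{"name": ..., "types": [...]}],
#' "object_assertions": [[prop, s, o]], "data_assertions":
#' [[prop, s, value, unit]]}`.
#'
#' @param path File path.
#' @param tbox TBox used to resolve type references.
#' @return A `cdmo_kb`.
#' @export
read_patients_json <- function(path, tbox) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  inds <- list()
  for (ind in obj$individuals) {
    inds[[ind$name]] <- unlist(ind$types) %||% character()
  }
  knowledge_base(
    tbox, inds,
    object_assertions = lapply(obj$object_assertions, unlist),
    data_assertions = lapply(obj$data_assertions, function(r) {
      r <- as.list(r)
      list(as.character(r[[1]]), as.character(r[[2]]),
           as.numeric(r[[3]]), if (length(r) >= 4L) as.character(r[[4]]) else "")
    })
  )
}

#' Write a patient ABox to JSON
#' @param kb A `cdmo_kb`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_patients_json <- function(kb, path) {
  obj <- list(
    individuals = lapply(names(kb$individuals), function(nm) {
      list(name = nm, types = as.list(kb$individuals[[nm]]))
    }),
    object_assertions = unname(apply(kb$object_assertions, 1L, as.list)),
    data_assertions = lapply(seq_len(nrow(kb$data_assertions)), function(i) {
      r <- kb$data_assertions[i, ]
      list(r$property, r$subject, r$value, r$unit)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
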