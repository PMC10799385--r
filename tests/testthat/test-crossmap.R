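test_that("name normalization collapses case, punctuation and word order", {
  expect_identical(normalize_name("Hyperosmolar hyperglycemic state"),
                   normalize_name("hyperglycemic hyperosmolar state"))
  expect_identical(normalize_name("Retinal disorder (disorder)"),
                   normalize_name("retinal disorder"))
  # idempotence
  k <- normalize_name("Fasting Blood-Glucose Measurement")
  expect_identical(normalize_name(k), k)

  # random case/punctuation/word-order perturbations all collapse to one key
  set.seed(21)
  base <- "hyperosmolar hyperglycemic state"
  key <- normalize_name(base)
  toks <- strsplit(base, " ")[[1]]
  puncts <- c(",", "-", ";", "  ", " (disorder) ")
  for (i in 1:100) {
    words <- sample(toks)
    words <- vapply(words, function(w) {
      flip <- sample(c(toupper, tolower, identity), 1)[[1]]
      flip(w)
    }, character(1))
    s <- paste(words, collapse = sample(puncts, 1))
    expect_identical(normalize_name(s), key, label = s)
  }

  # exact-order mode distinguishes word-order variants
  expect_false(identical(
    normalize_name("hyperosmolar hyperglycemic state", sort_tokens = FALSE),
    normalize_name("hyperglycemic hyperosmolar state", sort_tokens = FALSE)))
})

test_that("the lexical index covers every label of every target class", {
  tg <- make_target_ontology()
  lex <- build_lexical_index(tg$graph)
  for (con in tg$graph$concepts) {
    for (nm in con$labels_en) {
      expect_true(con$iri %in% lex$exact[[tolower(nm)]], label = nm)
      expect_true(con$iri %in% lex$normalized[[normalize_name(nm)]],
                  label = nm)
    }
  }
})

test_that("mapping proposal hits classes, not their children, and sorts hits", {
  tg <- make_target_ontology()
  lex <- build_lexical_index(tg$graph)
  # a concept whose English name is "fatigue": exact hit on Fatigue only,
  # never on its child Weakness
  fatigue <- concept("cdmo:test1", "疲劳", labels_en = "fatigue")
  m <- propose_mappings(fatigue, lex, "SNOMEDCT")
  expect_identical(m$target_id, "sct:84229001")
  expect_identical(m$match_type, "exact")

  # no English names: empty result plus a needs-translation note
  bare <- concept("cdmo:test2", "未翻译")
  expect_message(m2 <- propose_mappings(bare, lex), "needs translation")
  expect_identical(nrow(m2), 0L)

  # word-order variant resolves through the normalized key
  varia <- concept("cdmo:test3", "变体",
                   labels_en = "disorder retinal")
  m3 <- propose_mappings(varia, lex)
  expect_identical(m3$target_id, "sct:44730006")
  expect_identical(m3$match_type, "normalized")
})

test_that("proposals equal the all-pairs brute-force comparison", {
  set.seed(31)
  vocab <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
             "theta", "iota", "kappa")
  rand_name <- function() paste(sample(vocab, sample(1:3, 1)), collapse = " ")
  targets <- lapply(1:50, function(i) {
    concept(sprintf("t:%03d", i), sprintf("目标%03d", i),
            labels_en = rand_name())
  })
  tgraph <- ontology(targets, roots = sprintf("t:%03d", 1:50))
  lex <- build_lexical_index(tgraph)
  sources <- lapply(1:50, function(i) {
    concept(sprintf("s:%03d", i), sprintf("来源%03d", i),
            labels_en = rand_name())
  })
  for (con in sources) {
    got <- propose_mappings(con, lex, "T")
    # brute force over every (name, label) pair; per name, the normalized
    # key is consulted only when that name has no exact hit at all
    exact <- character(); norm <- character()
    for (nm in con$labels_en) {
      nm_exact <- character(); nm_norm <- character()
      for (tc in targets) {
        if (any(tolower(nm) == tolower(tc$labels_en))) {
          nm_exact <- c(nm_exact, tc$iri)
        } else if (any(normalize_name(nm) == normalize_name(tc$labels_en))) {
          nm_norm <- c(nm_norm, tc$iri)
        }
      }
      exact <- c(exact, nm_exact)
      if (!length(nm_exact)) norm <- c(norm, nm_norm)
    }
    want_exact <- sort(unique(exact))
    want_norm <- sort(setdiff(unique(norm), want_exact))
    expect_identical(got$target_id[got$match_type == "exact"], want_exact)
    expect_identical(got$target_id[got$match_type == "normalized"], want_norm)
  }
})

test_that("hierarchy induction recovers the planted subsumptions exactly", {
  tg <- make_target_ontology()
  src <- strip_edges(make_micro_ontology(), tg$planted_edges)
  targets <- list(SNOMEDCT = tg$graph)

  res <- induce_hierarchy(src, tg$mappings, targets, mode = "transitive",
                          apply = TRUE)
  acc <- res$edges[res$edges$status == "accepted", ]
  # precision = recall = 1 on the planted fixture
  expect_identical(edge_key(acc), edge_key(tg$planted_edges))
  # the worked retinopathy pair is among them
  expect_true(paste(iri_for_label("糖尿病视网膜病变"),
                    iri_for_label("视网膜病变"), sep = "->") %in%
                edge_key(acc))
  # the applied source graph is acyclic and asserts the planted edges
  expect_s3_class(validate_ontology(res$graph), "cdmo_ontology")
  for (i in seq_len(nrow(tg$planted_edges))) {
    expect_true(is_subclass_of(res$graph, tg$planted_edges$child_iri[i],
                               tg$planted_edges$parent_iri[i]))
  }
})

test_that("induction requires evidence from a single target ontology", {
  tg <- make_target_ontology()
  src <- strip_edges(make_micro_ontology(), tg$planted_edges)
  # split the mapping table across two ontology names: each pair of mapped
  # concepts now lives in different targets, so nothing can be proposed
  maps <- tg$mappings
  maps$target_ontology <- rep(c("A", "B"), length.out = nrow(maps))
  ed <- induce_hierarchy(src, maps, list(A = tg$graph, B = tg$graph))
  # every A-mapped concept's mapped ancestor sits in B and vice versa for
  # the alternating split of this fixture's chains, except pairs that land
  # in the same half; verify against brute force
  for (i in seq_len(nrow(ed))) {
    expect_identical(ed$target_ontology[i],
                     maps$target_ontology[maps$source_iri == ed$child_iri[i]])
  }
  # a genuinely subsumed pair split across two targets proposes nothing
  two_only <- tg$mappings[tg$mappings$source_iri %in%
                            iri_for_label(c("2型糖尿病", "糖尿病")), ]
  two_only$target_ontology <- c("A", "B")
  ed2 <- induce_hierarchy(src, two_only, list(A = tg$graph, B = tg$graph))
  expect_identical(nrow(ed2), 0L)
  # and in one target it proposes exactly the pair
  two_same <- two_only
  two_same$target_ontology <- "A"
  ed3 <- induce_hierarchy(src, two_same, list(A = tg$graph))
  expect_identical(edge_key(ed3[ed3$status == "accepted", ]),
                   paste(iri_for_label("2型糖尿病"), iri_for_label("糖尿病"),
                         sep = "->"))
})

test_that("direct-mode proposals are implied by transitive-mode results", {
  tg <- make_target_ontology()
  src <- strip_edges(make_micro_ontology(), tg$planted_edges)
  targets <- list(SNOMEDCT = tg$graph)
  dir_res <- induce_hierarchy(src, tg$mappings, targets, mode = "direct")
  tr_res <- induce_hierarchy(src, tg$mappings, targets, mode = "transitive",
                             apply = TRUE)
  acc_dir <- dir_res[dir_res$status == "accepted", ]
  for (i in seq_len(nrow(acc_dir))) {
    expect_true(is_subclass_of(tr_res$graph, acc_dir$child_iri[i],
                               acc_dir$parent_iri[i]))
  }
})

test_that("a corrupted mapping yields exactly its implied edges and is caught", {
  tg <- make_target_ontology()
  src <- strip_edges(make_micro_ontology(), tg$planted_edges)
  targets <- list(SNOMEDCT = tg$graph)
  # corrupt one mapping the way a lexical matcher would: point the parent
  # concept 视网膜病变 at the *child* target class (retinopathy due to
  # diabetes), reversing the planted subsumption evidence
  bad <- tg$mappings
  i_parent <- which(bad$source_iri == iri_for_label("视网膜病变"))
  i_child <- which(bad$source_iri == iri_for_label("糖尿病视网膜病变"))
  bad$target_id[i_parent] <- "sct:4855003"
  bad$target_id[i_child] <- "sct:44730006"
  res <- induce_hierarchy(src, bad, targets, apply = TRUE)
  acc <- res$edges[res$edges$status == "accepted", ]
  # the corrupted pair now induces the reversed edge; all other planted
  # edges are unaffected
  rev_edge <- paste(iri_for_label("视网膜病变"),
                    iri_for_label("糖尿病视网膜病变"), sep = "->")
  expect_true(rev_edge %in% edge_key(acc))
  expected <- tg$planted_edges
  k <- which(expected$child_iri == iri_for_label("糖尿病视网膜病变"))
  expected$child_iri[k] <- iri_for_label("视网膜病变")
  expected$parent_iri[k] <- iri_for_label("糖尿病视网膜病变")
  expect_identical(edge_key(acc), edge_key(expected))
  # the contradiction against planted truth is detectable: re-inducing from
  # the clean mappings on the corrupted graph reports a conflict, and no
  # cycle is ever applied
  expect_s3_class(validate_ontology(res$graph), "cdmo_ontology")
  res2 <- induce_hierarchy(res$graph, tg$mappings, targets)
  expect_true("rejected_conflict" %in% res2$status)
})

test_that("induction is deterministic and order-independent", {
  tg <- make_target_ontology()
  src <- strip_edges(make_micro_ontology(), tg$planted_edges)
  targets <- list(SNOMEDCT = tg$graph)
  base <- induce_hierarchy(src, tg$mappings, targets)
  set.seed(41)
  for (k in 1:5) {
    perm <- tg$mappings[sample(nrow(tg$mappings)), ]
    again <- induce_hierarchy(src, perm, targets)
    expect_identical(again, base)
  }
})

test_that("mapping CSV round-trips and tallies per target ontology", {
  set.seed(17)
  n <- 100
  recs <- mapping_records(
    source_iri = sprintf("cdmo:%08x", sample.int(1e6, n)),
    target_ontology = sample(c("SNOMEDCT", "NCIT", "HPO"), n, replace = TRUE),
    target_id = sprintf("id:%05d", sample.int(1e5, n)),
    match_type = sample(c("exact", "normalized", "manual"), n, replace = TRUE),
    similarity = ifelse(runif(n) < 0.5, NA, round(runif(n), 4))
  )
  td <- withr::local_tempdir()
  f <- file.path(td, "maps.csv")
  write_mappings(recs, f)
  back <- read_mappings(f)
  expect_equal(back, recs)

  # empty record list: header-only file
  f2 <- file.path(td, "empty.csv")
  write_mappings(mapping_records(), f2)
  expect_identical(length(readLines(f2)), 1L)
  expect_identical(nrow(read_mappings(f2)), 0L)

  # per-ontology counts match a hand tally
  ten <- recs[1:10, ]
  tab <- mapping_summary(ten)
  for (i in seq_len(nrow(tab))) {
    expect_identical(tab$n[i],
                     sum(ten$target_ontology == tab$target_ontology[i]))
  }
  expect_true(all(diff(tab$n) <= 0))

  # malformed rows are rejected with a line number
  writeLines(c("source_iri,target_ontology,target_id,match_type,similarity",
               "cdmo:1,SNOMEDCT,sct:1,bogus,"), f2)
  expect_error(read_mappings(f2), "line 2")
})

test_that("substance vs measurement double-mapping is flagged as a warning only", {
  tg <- make_target_ontology()
  # a concept mapped both under the procedure branch and under a
  # substance-ish branch of the same target
  maps <- mapping_records(
    source_iri = rep("cdmo:amb", 2), target_ontology = "SNOMEDCT",
    target_id = c("sct:70901006", "sct:372567009"), match_type = "manual")
  flagged <- flag_substance_measurement(
    maps, list(SNOMEDCT = tg$graph),
    substance_roots = list(SNOMEDCT = "sct:373873005"),
    procedure_roots = list(SNOMEDCT = "sct:71388002"))
  expect_identical(flagged, "cdmo:amb")
  # a cleanly mapped concept is not flagged
  clean <- mapping_records("cdmo:ok", "SNOMEDCT", "sct:70901006", "manual")
  expect_length(flag_substance_measurement(
    clean, list(SNOMEDCT = tg$graph),
    substance_roots = list(SNOMEDCT = "sct:373873005"),
    procedure_roots = list(SNOMEDCT = "sct:71388002")), 0L)
})
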