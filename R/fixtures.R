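# Deterministic, seeded generators for every input the other modules need:
# a bilingual micro-ontology, an English target ontology with planted
# subsumptions and its ground-truth mapping table, a corpus with controlled
# document frequencies, and patient ABoxes with known ground-truth
# inferences. Each generator runs on its own PRNG stream (seed + fixed
# offset), so adding one generator never shifts another's output, and every
# generator returns its planted truth alongside the data.

with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(expr)
}

micro_concept_table <- function() {
  # zh label | english names (;-separated) | parent zh labels | zh synonyms
  rows <- list(
    c("临床表现", "clinical finding", "", ""),
    c("过程", "procedure", "", ""),
    c("物质", "substance", "", ""),
    c("药物或生物制品", "pharmaceutical / biologic product;pharmaceutical biologic product", "", ""),
    c("可观察实体", "observable entity", "", ""),
    c("身体结构", "body structure", "", ""),
    c("疾病", "disease", "临床表现", ""),
    c("症状", "symptom", "临床表现", ""),
    c("糖代谢紊乱", "disorder of glucose regulation", "疾病", ""),
    c("糖尿病", "diabetes mellitus", "糖代谢紊乱", ""),
    c("低血糖", "hypoglycemia", "糖代谢紊乱", ""),
    c("高渗性高血糖状态", "hyperosmolar hyperglycemic state;hyperglycemic hyperosmolar status", "糖代谢紊乱", "高渗高血糖综合征"),
    c("1型糖尿病", "type 1 diabetes mellitus", "糖尿病", ""),
    c("2型糖尿病", "type 2 diabetes mellitus", "糖尿病", ""),
    c("特殊类型糖尿病", "special types of diabetes mellitus", "糖尿病", ""),
    c("妊娠糖尿病", "gestational diabetes mellitus", "糖尿病", ""),
    c("视网膜病变", "retinal disorder;retinopathy", "疾病", ""),
    c("糖尿病视网膜病变", "retinopathy due to diabetes;diabetic retinopathy", "视网膜病变", ""),
    c("酸中毒", "acidosis", "疾病", ""),
    c("乳酸性酸中毒", "lactic acidosis", "酸中毒", ""),
    c("肾病", "kidney disease", "疾病", "肾脏病"),
    c("肾功能不全", "renal insufficiency", "肾病", ""),
    c("慢性肾脏病", "chronic kidney disease", "肾病", ""),
    c("黑棘皮病", "acanthosis nigricans", "疾病", "黑棘皮症"),
    c("心肌梗死", "myocardial infarction", "疾病", "心肌梗塞"),
    c("多食", "polyphagia", "症状", ""),
    c("多尿", "polyuria", "症状", ""),
    c("多饮", "polydipsia", "症状", ""),
    c("体重减轻", "weight loss", "症状", ""),
    c("疲劳", "fatigue", "症状", ""),
    c("乏力", "malaise;weakness;lack of power", "症状", ""),
    c("检测", "measurement procedure", "过程", ""),
    c("血糖测定", "glucose measurement", "检测", ""),
    c("空腹血糖测定", "fasting blood glucose measurement", "血糖测定", ""),
    c("随机血糖测定", "random glucose measurement", "血糖测定", ""),
    c("肌酐测定", "creatinine measurement", "检测", ""),
    c("糖化血红蛋白测定", "hemoglobin A1c measurement", "检测", ""),
    c("生活方式干预", "lifestyle therapy;lifestyle intervention", "过程", ""),
    c("肌酐", "creatinine", "物质", ""),
    c("葡萄糖", "glucose", "物质", ""),
    c("糖化血红蛋白", "glycated hemoglobin", "物质", ""),
    c("含糖食物", "sugary food", "物质", ""),
    c("降糖药", "hypoglycemic agent", "药物或生物制品", ""),
    c("二甲双胍", "metformin", "降糖药", ""),
    c("胰高糖素样肽-1受体激动剂", "glucagon like peptide 1 receptor agonist;glucagon-like peptide-1 receptor agonist", "降糖药", ""),
    c("奥利司他", "orlistat", "药物或生物制品", ""),
    c("体重指数", "body mass index", "可观察实体", ""),
    c("患者", "patient", "可观察实体", ""),
    c("视网膜", "retina", "身体结构", ""),
    c("肾脏", "kidney", "身体结构", "")
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(zh = r[1], en = r[2], parent = r[3], syn = r[4],
               stringsAsFactors = FALSE)
  }))
}

#' Generate the bilingual micro-ontology
#'
#' A fixed, fully curated ~50-concept diabetes ontology under a SNOMED-style
#' first level (clinical finding, procedure, substance,
#' pharmaceutical/biologic product, observable entity, body structure). It
#' contains every class the shipped clinical-decision rules mention, and
#' every concept carries a Chinese preferred label, at least one English
#' name and a sourced definition, so the graph passes [qc_report()] cleanly.
#' Content is deliberately hard-coded — the worked clinical scenarios must
#' never depend on randomness — so `seed` only seeds the definition-source
#' rotation.
#'
#' @param seed Integer seed (default 1).
#' @return A `cdmo_ontology`.
#' @export
make_micro_ontology <- function(seed = 1L) {
  tab <- micro_concept_table()
  src_cycle <- definition_sources()[c(1, 2, 3, 4, 1, 2)]
  concepts <- lapply(seq_len(nrow(tab)), function(i) {
    zh <- tab$zh[i]
    en <- strsplit(tab$en[i], ";", fixed = TRUE)[[1]]
    syn <- if (nzchar(tab$syn[i])) strsplit(tab$syn[i], ";", fixed = TRUE)[[1]]
           else character()
    parents <- if (nzchar(tab$parent[i])) iri_for_label(tab$parent[i])
               else character()
    ann <- character()
    if (zh == "空腹血糖测定") {
      ann <- c("诊断切点" = "7.0 mmol/L", "正常参考值" = "3.9-6.1 mmol/L")
    }
    if (zh == "体重指数") {
      ann <- c("正常参考值" = "18.5-23.9 kg/m2")
    }
    concept(
      iri = iri_for_label(zh), label_zh = zh, labels_en = en,
      synonyms_zh = syn,
      definition = definition_record(
        sprintf("%s（%s）：临床实践指南所涉概念。", zh, en[1]),
        src_cycle[(i - 1L) %% length(src_cycle) + 1L]),
      annotations = ann, parents = parents
    )
  })
  cf <- iri_for_label("临床表现"); pr <- iri_for_label("过程")
  drug <- iri_for_label("药物或生物制品"); pat <- iri_for_label("患者")
  props <- list(
    property_def("并发症", "has complication", "object",
                 domain = c(cf, pr), range = cf),
    property_def("常见并发症", "has common complications", "object",
                 parent = "并发症", domain = c(cf, pr), range = cf),
    property_def("急性并发症", "has acute complications", "object",
                 parent = "并发症", domain = c(cf, pr), range = cf),
    property_def("慢性并发症", "has chronic complications", "object",
                 parent = "并发症", domain = c(cf, pr), range = cf),
    property_def("治疗药物", "therapeutic drug", "object",
                 domain = c(cf, pr), range = drug),
    property_def("一线药物", "first line therapeutic drug", "object",
                 parent = "治疗药物", domain = c(cf, pr), range = drug),
    property_def("二线药物", "second line therapeutic drug", "object",
                 parent = "治疗药物", domain = c(cf, pr), range = drug),
    property_def("症状", "has symptom", "object", domain = cf, range = cf),
    property_def("典型症状", "has major feature", "object",
                 parent = "症状", domain = cf, range = cf),
    property_def("常见症状", "has common symptom", "object",
                 parent = "症状", domain = cf, range = cf),
    # patient-level relations used by the decision rules
    property_def("患者有症状", "patient_has_symptom", "object",
                 domain = pat, range = cf),
    property_def("患者有检查", "patient_has_test", "object",
                 domain = pat, range = pr),
    property_def("患者有诊断", "patient_has_diagnosis", "object",
                 domain = pat, range = cf),
    property_def("患者有可观察实体", "patient_has_observable_entity", "object",
                 domain = pat, range = iri_for_label("可观察实体")),
    property_def("患者有治疗", "patient_has_therapy", "object",
                 domain = pat, range = pr),
    property_def("患者有治疗药物", "patient_has_therapy_drug", "object",
                 domain = pat, range = drug),
    property_def("患者有禁忌药物", "patient_has_constraindication_drug",
                 "object", domain = pat, range = drug),
    property_def("增加摄入", "increase_intake", "object",
                 domain = pat, range = iri_for_label("物质")),
    property_def("正常参考值", "normal reference value", "annotation"),
    property_def("诊断切点", "diagnostic cut-off value", "annotation")
  )
  roots <- iri_for_label(c("临床表现", "过程", "物质", "药物或生物制品",
                           "可观察实体", "身体结构"))
  ontology(concepts, props, roots = roots)
}

#' Generate the English target ontology and its ground-truth mappings
#'
#' An English-labeled target (SNOMED-like ids under an `sct:` prefix) whose
#' hierarchy plants 14 child-parent pairs aligned to micro-ontology
#' concepts — including the retinal-disorder / retinopathy-due-to-diabetes
#' pair — plus unmapped distractor classes (a Fatigue branch with Weakness
#' and Asthenia children). The returned mapping table and planted edge list
#' are the ground truth for hierarchy-induction recovery tests: the planted
#' edges are exactly the transitive reduction of the target subsumptions
#' restricted to mapped classes, by construction.
#'
#' @param seed Integer seed (structure is fixed; reserved for future noise).
#' @return List with `graph` (the target `cdmo_ontology`), `mappings` (a
#'   `cdmo_mappings` table, source micro-IRI -> target id), and
#'   `planted_edges` (`data.frame` with `child_iri`, `parent_iri` in the
#'   micro-ontology).
#' @export
make_target_ontology <- function(seed = 1L) {
  # id | label | parent ids (;-separated)
  rows <- list(
    c("sct:404684003", "Clinical finding", ""),
    c("sct:71388002", "Procedure", ""),
    c("sct:373873005", "Pharmaceutical / biologic product", ""),
    c("sct:126877002", "Disorder of glucose regulation", "sct:404684003"),
    c("sct:73211009", "Diabetes mellitus", "sct:126877002"),
    c("sct:46635009", "Diabetes mellitus type 1", "sct:73211009"),
    c("sct:44054006", "Diabetes mellitus type 2", "sct:73211009"),
    c("sct:8801005", "Secondary diabetes mellitus", "sct:73211009"),
    c("sct:11687002", "Gestational diabetes mellitus", "sct:73211009"),
    c("sct:302866003", "Hypoglycemia", "sct:126877002"),
    c("sct:44730006", "Retinal disorder", "sct:404684003"),
    c("sct:4855003", "Retinopathy due to diabetes", "sct:44730006"),
    c("sct:51387008", "Acidosis", "sct:404684003"),
    c("sct:91273001", "Lactic acidosis", "sct:51387008"),
    c("sct:122869004", "Measurement procedure", "sct:71388002"),
    c("sct:36048009", "Glucose measurement", "sct:122869004"),
    c("sct:87433001", "Fasting blood glucose measurement", "sct:36048009"),
    c("sct:271061004", "Random glucose measurement", "sct:36048009"),
    c("sct:70901006", "Creatinine measurement", "sct:122869004"),
    c("sct:372711004", "Hypoglycemic agent", "sct:373873005"),
    c("sct:372567009", "Metformin", "sct:372711004"),
    c("sct:734595009", "Glucagon like peptide 1 receptor agonist", "sct:372711004"),
    # unmapped distractors for the name-search examples
    c("sct:84229001", "Fatigue", "sct:404684003"),
    c("sct:13791008", "Asthenia", "sct:84229001"),
    c("sct:26544005", "Weakness", "sct:84229001")
  )
  concepts <- lapply(rows, function(r) {
    parents <- if (nzchar(r[3])) strsplit(r[3], ";", fixed = TRUE)[[1]]
               else character()
    concept(iri = r[1], label_zh = r[2], labels_en = r[2],
            definition = definition_record(
              sprintf("%s: a class of the English target hierarchy.", r[2]),
              "manual"),
            parents = parents)
  })
  graph <- ontology(concepts,
                    roots = c("sct:404684003", "sct:71388002", "sct:373873005"))
  map <- list(
    c("糖代谢紊乱", "sct:126877002"),
    c("糖尿病", "sct:73211009"),
    c("1型糖尿病", "sct:46635009"),
    c("2型糖尿病", "sct:44054006"),
    c("特殊类型糖尿病", "sct:8801005"),
    c("妊娠糖尿病", "sct:11687002"),
    c("低血糖", "sct:302866003"),
    c("视网膜病变", "sct:44730006"),
    c("糖尿病视网膜病变", "sct:4855003"),
    c("酸中毒", "sct:51387008"),
    c("乳酸性酸中毒", "sct:91273001"),
    c("检测", "sct:122869004"),
    c("血糖测定", "sct:36048009"),
    c("空腹血糖测定", "sct:87433001"),
    c("随机血糖测定", "sct:271061004"),
    c("肌酐测定", "sct:70901006"),
    c("降糖药", "sct:372711004"),
    c("二甲双胍", "sct:372567009"),
    c("胰高糖素样肽-1受体激动剂", "sct:734595009")
  )
  mappings <- mapping_records(
    source_iri = iri_for_label(vapply(map, `[[`, character(1), 1L)),
    target_ontology = "SNOMEDCT",
    target_id = vapply(map, `[[`, character(1), 2L),
    match_type = "manual"
  )
  planted <- list(
    c("糖尿病", "糖代谢紊乱"),
    c("1型糖尿病", "糖尿病"),
    c("2型糖尿病", "糖尿病"),
    c("特殊类型糖尿病", "糖尿病"),
    c("妊娠糖尿病", "糖尿病"),
    c("低血糖", "糖代谢紊乱"),
    c("糖尿病视网膜病变", "视网膜病变"),
    c("乳酸性酸中毒", "酸中毒"),
    c("血糖测定", "检测"),
    c("空腹血糖测定", "血糖测定"),
    c("随机血糖测定", "血糖测定"),
    c("肌酐测定", "检测"),
    c("二甲双胍", "降糖药"),
    c("胰高糖素样肽-1受体激动剂", "降糖药")
  )
  planted_edges <- data.frame(
    child_iri = iri_for_label(vapply(planted, `[[`, character(1), 1L)),
    parent_iri = iri_for_label(vapply(planted, `[[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
  list(graph = graph, mappings = mappings, planted_edges = planted_edges)
}

#' Strip a set of is_a edges from a graph
#'
#' Used to rebuild the pre-induction state of a source ontology whose
#' curated hierarchy already contains the planted edges, so induction
#' recovery can be measured from a blank slate.
#'
#' @param graph A `cdmo_ontology`.
#' @param edges `data.frame` with columns `child_iri`, `parent_iri`.
#' @return The graph without those parent links.
#' @export
strip_edges <- function(graph, edges) {
  for (i in seq_len(nrow(edges))) {
    ch <- edges$child_iri[i]
    graph$concepts[[ch]]$parents <-
      setdiff(graph$concepts[[ch]]$parents, edges$parent_iri[i])
  }
  graph
}

#' Generate a synthetic corpus with controlled document frequencies
#'
#' Plants each term in a chosen number of distinct documents (filler text
#' contains no lexicon surface), adds grade/degree noise ("1级", "3期") and
#' stoplist noise ("全部") at high document frequency, one well-attested
#' term deliberately absent from the lexicon-presence set, and a synonym
#' pair sharing the English name "acanthosis nigricans". The ground truth
#' records, per surface, its exact document set — recomputed independently
#' by naive substring scan over the final texts — and which surfaces must
#' survive the exclusion + lexicon-presence + >= `min_docs` filter.
#'
#' @param seed Integer seed.
#' @param n_docs Number of documents (default 20).
#' @param min_docs Document-frequency threshold the truth table is computed
#'   for (default 3).
#' @return List with `corpus` (list of documents), `lexicon` (matcher
#'   surfaces), `lexicon_presence`, `english_names`, `truth`
#'   (`data.frame` surface/doc_frequency/in_lexicon/excluded/survives) and
#'   `survivors` (character vector of canonical surviving surfaces).
#' @export
make_corpus <- function(seed = 1L, n_docs = 20L, min_docs = 3L) {
  planted <- c(
    "糖尿病" = 5L, "2型糖尿病" = 4L, "低血糖" = 3L, "二甲双胍" = 3L,
    "视网膜病变" = 2L, "乏力" = 1L,
    "黑棘皮症" = 3L, "黑棘皮病" = 3L,
    "运动疗法" = 4L,            # attested but not in the presence set
    "1级" = 4L, "3期" = 3L, "全部" = 5L
  )
  lexicon <- names(planted)
  presence <- setdiff(lexicon, "运动疗法")
  docs <- with_stream(seed, 101L, {
    assignment <- lapply(names(planted), function(term) {
      sort(sample.int(n_docs, planted[[term]]))
    })
    names(assignment) <- names(planted)
    lapply(seq_len(n_docs), function(i) {
      terms <- names(planted)[vapply(assignment, function(a) i %in% a,
                                     logical(1))]
      body <- if (length(terms)) {
        paste0(vapply(terms, function(t) paste0("指南指出", t, "需要关注。"),
                      character(1)), collapse = "")
      } else ""
      list(doc_id = sprintf("doc%02d", i),
           text = paste0("资料与方法。", body, "结论。"),
           source = "synthetic-guideline")
    })
  })
  # independent bookkeeping: naive substring scan over the final texts
  texts <- vapply(docs, `[[`, character(1), "text")
  doc_sets <- lapply(lexicon, function(term) {
    which(vapply(texts, function(tx) grepl(term, tx, fixed = TRUE),
                 logical(1)))
  })
  names(doc_sets) <- lexicon
  dfreq <- vapply(doc_sets, length, integer(1))
  excluded <- grepl(grade_degree_pattern(), lexicon, perl = TRUE) |
    lexicon %in% default_stoplist()
  survives <- !excluded & lexicon %in% presence & dfreq >= min_docs
  truth <- data.frame(surface = lexicon, doc_frequency = unname(dfreq),
                      in_lexicon = lexicon %in% presence,
                      excluded = unname(excluded),
                      survives = unname(survives),
                      stringsAsFactors = FALSE)
  english_names <- list(
    "黑棘皮症" = "acanthosis nigricans",
    "黑棘皮病" = "acanthosis nigricans"
  )
  surv <- truth$surface[truth$survives]
  # the synonym pair collapses onto its lexicographically smallest member
  merge_group <- intersect(surv, c("黑棘皮病", "黑棘皮症"))
  if (length(merge_group) == 2L) {
    surv <- setdiff(surv, utf8_sort(merge_group)[2L])
  }
  list(corpus = docs, lexicon = lexicon, lexicon_presence = presence,
       english_names = english_names, truth = truth,
       doc_sets = lapply(doc_sets, function(ix) sprintf("doc%02d", ix)),
       survivors = utf8_sort(surv))
}

#' Generate patient ABoxes with known ground-truth inferences
#'
#' Builds a knowledge base over the micro-ontology containing one canonical
#' individual per diagnosable/recommendable class (diabetes mellitus, type 2
#' diabetes mellitus, lifestyle therapy, orlistat, GLP-1 receptor agonist,
#' metformin, sugary food, glucose, hypoglycemia, renal insufficiency), the
#' shared symptom individuals, and `n` patients. The first two patients are
#' the literal worked scenarios — four symptoms with fasting blood glucose
#' 8.0 mmol/L, and a type 2 diabetes patient with body-mass index 28 — and
#' are hard-coded, never sampled. Remaining patients draw random symptom
#' subsets and place test values at threshold + a sampled margin (0 included,
#' so exactly-at-threshold cases occur).
#'
#' The ground truth lists, per patient, every assertion the four shipped
#' rules must derive, computed directly from the construction (explicit
#' per-rule conditions including the diagnosis-then-therapy chaining), not
#' by the inference engine.
#'
#' @param seed Integer seed.
#' @param n Total number of patients (>= 2; default 10).
#' @param margins Numeric offsets added to the 7.0 mmol/L and BMI 27
#'   thresholds (default `c(-1, -0.5, -0.1, 0, 0.1, 0.5, 1)`).
#' @return List with `kb` (a `cdmo_kb`), `truth` (named list: patient ->
#'   character vector of expected derived-assertion keys
#'   `"object|property|subject|object"`), and `patients` (bookkeeping
#'   `data.frame`).
#' @export
make_patients <- function(seed = 1L, n = 10L,
                          margins = c(-1, -0.5, -0.1, 0, 0.1, 0.5, 1)) {
  stopifnot(n >= 2L)
  g <- make_micro_ontology(seed)
  lab <- function(x) iri_for_label(x)
  canonical <- list(
    diabetes_mellitus = "糖尿病",
    type_2_diabetes_mellitus = "2型糖尿病",
    lifestyle_therapy = "生活方式干预",
    orlistat = "奥利司他",
    glp1_receptor_agonist = "胰高糖素样肽-1受体激动剂",
    metformin = "二甲双胍",
    sugary_food = "含糖食物",
    glucose = "葡萄糖",
    hypoglycemia = "低血糖",
    renal_insufficiency = "肾功能不全"
  )
  symptoms <- c("polyphagia" = "多食", "polyuria" = "多尿",
                "polydipsia" = "多饮", "weight_loss" = "体重减轻")
  individuals <- c(
    lapply(canonical, function(zh) lab(zh)),
    lapply(as.list(symptoms), function(zh) lab(zh))
  )
  oa <- list(); da <- list()
  pats <- list()
  add_patient <- function(name, symptom_subset, fbg = NULL, bmi = NULL,
                          diagnoses = character()) {
    individuals[[name]] <<- lab("患者")
    for (s in symptom_subset) {
      oa[[length(oa) + 1L]] <<- c("patient_has_symptom", name, s)
    }
    if (!is.null(fbg)) {
      test <- paste0("fbg_", name)
      individuals[[test]] <<- lab("空腹血糖测定")
      oa[[length(oa) + 1L]] <<- c("patient_has_test", name, test)
      da[[length(da) + 1L]] <<- list("test_has_value", test, fbg, "mmol/L")
    }
    if (!is.null(bmi)) {
      obs <- paste0("bmi_", name)
      individuals[[obs]] <<- lab("体重指数")
      oa[[length(oa) + 1L]] <<- c("patient_has_observable_entity", name, obs)
      da[[length(da) + 1L]] <<- list("observable_entity_has_value", obs, bmi,
                                     "kg/m2")
    }
    for (d in diagnoses) {
      oa[[length(oa) + 1L]] <<- c("patient_has_diagnosis", name, d)
    }
    pats[[name]] <<- list(symptoms = symptom_subset, fbg = fbg, bmi = bmi,
                          asserted_diagnoses = diagnoses)
  }
  # the two literal worked scenarios, always present and never sampled
  add_patient("patient_a", names(symptoms), fbg = 8.0)
  add_patient("patient_b", character(), bmi = 28,
              diagnoses = "type_2_diabetes_mellitus")
  if (n > 2L) {
    with_stream(seed, 202L, {
      for (k in seq_len(n - 2L)) {
        name <- sprintf("patient_%02d", k)
        n_sym <- sample(0:4, 1L)
        subset <- sample(names(symptoms), n_sym)
        fbg <- if (stats::runif(1) < 0.8) 7.0 + sample(margins, 1L)
        bmi <- if (stats::runif(1) < 0.5) 27 + sample(margins, 1L)
        diagnoses <- character()
        if (stats::runif(1) < 0.3) diagnoses <- "type_2_diabetes_mellitus"
        if (stats::runif(1) < 0.2) {
          diagnoses <- c(diagnoses, "renal_insufficiency")
        }
        if (stats::runif(1) < 0.2) diagnoses <- c(diagnoses, "hypoglycemia")
        add_patient(name, subset, fbg = fbg, bmi = bmi, diagnoses = diagnoses)
      }
    })
  }
  kb <- knowledge_base(g, individuals, object_assertions = oa,
                       data_assertions = da)
  # ground truth by construction: explicit conditions per printed rule,
  # including the Diagnosis_1 -> Therapy_1 chaining through a derived
  # type-2 diagnosis
  okey <- function(p, s, o) paste("object", p, s, o, sep = "|")
  truth <- list()
  for (name in names(pats)) {
    p <- pats[[name]]
    expected <- character()
    diagnosed <- p$asserted_diagnoses
    diag1 <- length(p$symptoms) == 4L && !is.null(p$fbg) && p$fbg >= 7.0
    if (diag1) {
      # every individual whose type is subsumed by diabetes mellitus
      for (d in c("diabetes_mellitus", "type_2_diabetes_mellitus")) {
        if (!d %in% diagnosed) {
          expected <- c(expected, okey("patient_has_diagnosis", name, d))
          diagnosed <- c(diagnosed, d)
        }
      }
    }
    therapy1 <- "type_2_diabetes_mellitus" %in% diagnosed &&
      !is.null(p$bmi) && p$bmi >= 27
    if (therapy1) {
      expected <- c(expected,
                    okey("patient_has_therapy", name, "lifestyle_therapy"),
                    okey("patient_has_therapy_drug", name, "orlistat"),
                    okey("patient_has_therapy_drug", name,
                         "glp1_receptor_agonist"))
    }
    if ("type_2_diabetes_mellitus" %in% diagnosed &&
        "renal_insufficiency" %in% diagnosed) {
      expected <- c(expected,
                    okey("patient_has_constraindication_drug", name,
                         "metformin"))
    }
    if ("hypoglycemia" %in% diagnosed) {
      expected <- c(expected,
                    okey("increase_intake", name, "sugary_food"),
                    okey("increase_intake", name, "glucose"))
    }
    truth[[name]] <- expected
  }
  book <- do.call(rbind, lapply(names(pats), function(nm) {
    p <- pats[[nm]]
    data.frame(patient = nm, n_symptoms = length(p$symptoms),
               fbg = if (is.null(p$fbg)) NA_real_ else p$fbg,
               bmi = if (is.null(p$bmi)) NA_real_ else p$bmi,
               asserted = paste(p$asserted_diagnoses, collapse = ";"),
               n_expected = length(truth[[nm]]),
               stringsAsFactors = FALSE)
  }))
  list(kb = kb, truth = truth, patients = book)
}

#' Path to the shipped clinical-decision rule file
#'
#' The four printed diagnosis/therapy/contraindication/diet rules in the
#' plain-text dialect, each with its natural-language explanation attached
#' as a comment.
#'
#' @return File path inside the installed package.
#' @export
diabetes_rules_path <- function() {
  system.file("rules", "diabetes_core.rules", package = "cdmo",
              mustWork = TRUE)
}

#' Write every fixture to a directory
#'
#' Ontology (Turtle + JSON), target ontology (Turtle), mapping CSV, corpus
#' (JSONL), patients (JSON) and ground truth (JSON), all derived from one
#' seed.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_fixtures <- function(seed = 1L, out_dir = "fixtures") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- make_micro_ontology(seed)
  save_ontology(g, file.path(out_dir, "micro_ontology.ttl"), "turtle")
  save_ontology(g, file.path(out_dir, "micro_ontology.json"), "json")
  tg <- make_target_ontology(seed)
  save_ontology(tg$graph, file.path(out_dir, "target_ontology.ttl"), "turtle")
  write_mappings(tg$mappings, file.path(out_dir, "mappings.csv"))
  cp <- make_corpus(seed)
  write_corpus_jsonl(cp$corpus, file.path(out_dir, "corpus.jsonl"))
  pat <- make_patients(seed)
  write_patients_json(pat$kb, file.path(out_dir, "patients.json"))
  truth <- list(
    planted_edges = tg$planted_edges,
    corpus_truth = cp$truth,
    corpus_survivors = cp$survivors,
    patient_truth = pat$truth
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "ground_truth.json"), useBytes = TRUE)
  invisible(out_dir)
}
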