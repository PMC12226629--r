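## ---------------------------------------------------------------------------
## Seeded template-grammar generator of labelled synthetic neck/thyroid
## ultrasound reports. Every phrase in the banks carries the class labels it
## implies, so each generated report has an exact ground-truth label vector
## by construction; phrases known to defeat purely lexical rules (hedged
## wording, hypothetical findings) are tagged ambiguous and excluded from
## exact-agreement checks.
## ---------------------------------------------------------------------------

#' Class names of the packaged thyroid strategy, in order
#' @return Character vector of the fourteen class names.
#' @export
thyroid_classes <- function() {
  c("Thyroid examination", "Lymph node examination", "Thyroid nodule(s)",
    "Multiple thyroid nodules", "Altered thyroid echotexture", "Goitre",
    "Previous thyroid surgery", "BTA U1", "BTA U2", "BTA U3", "BTA U4",
    "BTA U5", "Solitary thyroid nodule", "Normal thyroid")
}

# A phrase bank entry: text, the label keys it implies, ambiguity flag.
ph <- function(text, labels = character(0), ambiguous = FALSE) {
  list(text = text, labels = labels, ambiguous = ambiguous)
}

synth_banks <- function() {
  list(
    opening = list(
      ph("Ultrasound of the thyroid was performed.", "exam"),
      ph("Ultrasound assessment of the thyroid gland.", "exam"),
      ph("The thyroid gland was examined with high frequency ultrasound.",
         "exam")),
    normal_desc = list(
      ph("The thyroid gland is normal in size and outline with homogeneous echotexture.",
         "exam"),
      ph("Both lobes of the thyroid appear normal.", "exam"),
      ph("The thyroid is of normal size with no focal abnormality.", "exam")),
    negated_nodule = list(
      ph("There are no thyroid nodules.", "exam"),
      ph("Thyroid nodules were not observed.", "exam"),
      ph("No discrete nodules are seen within the thyroid.", "exam")),
    solitary = list(
      ph("There is a solitary well defined nodule in the right lobe measuring 12 x 8 mm.",
         "nodule"),
      ph("A single hypoechoic nodule is seen in the left lobe.", "nodule"),
      ph("A 9 mm colloid nodule is noted in the isthmus.", "nodule")),
    multiple = list(
      ph("Multiple nodules are seen throughout both lobes.",
         c("nodule", "multiple")),
      ph("The thyroid contains several nodules bilaterally.",
         c("exam", "nodule", "multiple")),
      ph("Appearances are in keeping with a multinodular goitre.",
         c("nodule", "multiple", "goitre")),
      ph("Appearances of a multinodular goitre (MNG) with a dominant nodule in the left lobe.",
         c("nodule", "multiple", "goitre"))),
    grade_solitary = list(
      ph("The nodule has benign features, BTA U2.", c("nodule", "u2")),
      ph("The nodule is indeterminate, graded U3.", c("nodule", "u3")),
      ph("The nodule has suspicious features (U4).", c("nodule", "u4")),
      ph("Features are highly concerning for malignancy, BTA U5.", "u5")),
    grade_multiple = list(
      ph("The dominant nodule has benign features, BTA U2.",
         c("nodule", "u2")),
      ph("The dominant nodule is graded U3.", c("nodule", "u3")),
      ph("The largest nodule has suspicious features (U4).",
         c("nodule", "u4"))),
    grade_u1 = list(
      ph("Graded U1.", "u1")),
    echo = list(
      ph("The thyroid is diffusely heterogeneous in echotexture.",
         c("exam", "echo")),
      ph("Features are consistent with thyroiditis.", c("exam", "echo")),
      ph("The gland is heterogeneous and inflamed, in keeping with thyroiditis.",
         c("exam", "echo"))),
    goitre = list(
      ph("The thyroid gland is diffusely enlarged.", c("exam", "goitre")),
      ph("There is a large goitre extending retrosternally.", "goitre")),
    surgery_findings = list(
      ph("The right lobe is absent in keeping with previous lobectomy.",
         "surgery"),
      ph("Changes in the thyroid bed consistent with previous surgery.",
         c("exam", "surgery"))),
    surgery_history = list(
      ph("Previous total thyroidectomy for papillary carcinoma.", "surgery"),
      ph("Prior left lobectomy.", "surgery")),
    lymph = list(
      ph("No abnormal cervical lymph nodes.", "lymph"),
      ph("Normal appearance of the cervical lymph nodes bilaterally.",
         "lymph"),
      ph("A few small reactive lymph nodes are noted in level II.", "lymph")),
    distractor = list(
      ph("A small left parotid cyst is noted."),
      ph("Simple cyst within the submandibular gland."),
      ph("A thyroglossal cyst is demonstrated in the midline."),
      ph("The salivary glands appear normal."),
      ph("Bilateral parotid cysts are present.")),
    ambiguous = list(
      ph("The thyroid gland appears slightly enlarged.", "exam",
         ambiguous = TRUE),
      ph("Query small nodule in the left lobe.", character(0),
         ambiguous = TRUE),
      ph("A thyroglossal duct cyst is noted.", character(0),
         ambiguous = TRUE)),
    history = list(
      ph("Neck lump."),
      ph("Difficulty swallowing for several months."),
      ph("Routine surveillance."),
      ph("Hypothyroidism on levothyroxine."),
      ph("Referred by GP with neck swelling."),
      ph("Referred for surgery.")),
    filler = list(
      ph("The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm."),
      ph("The isthmus measures 2.5 mm."),
      ph("The trachea is central and the carotid arteries are patent."),
      ph("Normal vascularity on colour Doppler."),
      ph("No focal collection is seen."),
      ph("The visualised soft tissues of the neck are unremarkable."),
      ph("Comparison was made with the previous examination."),
      ph("The appearances are stable."))
  )
}

synth_defaults <- function() {
  list(
    p_thyroid_exam = 0.85,   # remainder are non-thyroid neck studies
    p_nodule = c(none = 0.45, solitary = 0.30, multiple = 0.25),
    p_negated_mention = 0.5, # negated nodule sentence when none present
    p_echo = 0.15,
    p_goitre = 0.12,
    p_surgery = 0.12,
    p_lymph = 0.5,
    p_distractor = 0.2,
    p_grading = 0.5,         # BTA grade stated when nodules present
    p_u1 = 0.15,             # U1 stated on nodule-free thyroid exams
    p_ambiguous = 0.08,
    p_headerless = 0.1,      # fully unstructured reports (no headers)
    mean_words = 93,         # mean total report length, in words
    sd_words = 12,
    force_solitary = FALSE,
    force_multiple = FALSE
  )
}

count_words <- function(text) {
  length(strsplit(trimws(text), "\\s+")[[1]])
}

# Assemble one report; returns text, label keys, ambiguous flag, headerless.
synth_report <- function(banks, cfg) {
  pick <- function(bank) bank[[sample.int(length(bank), 1L)]]
  keys <- character(0)
  ambiguous <- FALSE
  findings <- list()
  history <- list()
  add <- function(entry, where = "findings") {
    keys <<- union(keys, entry$labels)
    ambiguous <<- ambiguous || entry$ambiguous
    if (where == "findings") {
      findings[[length(findings) + 1L]] <<- entry$text
    } else {
      history[[length(history) + 1L]] <<- entry$text
    }
  }
  headerless <- stats::runif(1) < cfg$p_headerless
  thyroid_exam <- stats::runif(1) < cfg$p_thyroid_exam

  if (!headerless) add(pick(banks$history), "history")

  if (thyroid_exam) {
    add(pick(banks$opening))
    status <- if (cfg$force_solitary) "solitary"
      else if (cfg$force_multiple) "multiple"
      else sample(names(cfg$p_nodule), 1L, prob = cfg$p_nodule)
    if (status == "none") {
      if (stats::runif(1) < cfg$p_negated_mention) {
        add(pick(banks$negated_nodule))
      } else {
        add(pick(banks$normal_desc))
      }
      if (stats::runif(1) < cfg$p_u1) add(pick(banks$grade_u1))
    } else if (status == "solitary") {
      add(pick(banks$solitary))
      if (stats::runif(1) < cfg$p_grading) add(pick(banks$grade_solitary))
    } else {
      add(pick(banks$multiple))
      if (stats::runif(1) < cfg$p_grading) add(pick(banks$grade_multiple))
    }
    if (stats::runif(1) < cfg$p_echo) add(pick(banks$echo))
    if (stats::runif(1) < cfg$p_goitre) add(pick(banks$goitre))
    if (stats::runif(1) < cfg$p_surgery) {
      if (headerless || stats::runif(1) < 0.5) {
        add(pick(banks$surgery_findings))
      } else {
        add(pick(banks$surgery_history), "history")
      }
    }
    if (stats::runif(1) < cfg$p_ambiguous) add(pick(banks$ambiguous))
  } else {
    add(pick(banks$distractor))
    if (stats::runif(1) < 0.5) add(pick(banks$distractor))
  }
  if (stats::runif(1) < cfg$p_lymph) add(pick(banks$lymph))
  if (thyroid_exam && stats::runif(1) < cfg$p_distractor) {
    add(pick(banks$distractor))
  }

  # pad with neutral filler towards the target report length
  target <- max(20, round(stats::rnorm(1, cfg$mean_words, cfg$sd_words)))
  fill_order <- sample.int(length(banks$filler))
  fi <- 1L
  current <- paste(c(unlist(history), unlist(findings)), collapse = " ")
  while (count_words(current) < target && fi <= length(fill_order)) {
    entry <- banks$filler[[fill_order[fi]]]
    findings[[length(findings) + 1L]] <- entry$text
    current <- paste(current, entry$text)
    fi <- fi + 1L
  }

  findings_text <- paste(unlist(findings), collapse = " ")
  text <- if (headerless) {
    findings_text
  } else {
    paste0("Clinical history: ", paste(unlist(history), collapse = " "),
           "\n\nFindings: ", findings_text)
  }
  list(text = text, keys = keys, ambiguous = ambiguous)
}

# Expand label keys into the full 14-class ground-truth vector, applying the
# derived-class identities (solitary = nodule and not multiple; normal =
# examination with no focal or diffuse abnormality) and the grading-implies-
# nodule consistency rule.
keys_to_labels <- function(keys) {
  key_map <- c(exam = "Thyroid examination", lymph = "Lymph node examination",
               nodule = "Thyroid nodule(s)", multiple = "Multiple thyroid nodules",
               echo = "Altered thyroid echotexture", goitre = "Goitre",
               surgery = "Previous thyroid surgery", u1 = "BTA U1",
               u2 = "BTA U2", u3 = "BTA U3", u4 = "BTA U4", u5 = "BTA U5")
  lab <- stats::setNames(rep(FALSE, length(thyroid_classes())),
                         thyroid_classes())
  lab[key_map[intersect(keys, names(key_map))]] <- TRUE
  if (any(lab[c("BTA U2", "BTA U3", "BTA U4", "BTA U5")]) ||
      lab[["Multiple thyroid nodules"]]) {
    lab[["Thyroid nodule(s)"]] <- TRUE
  }
  lab[["Solitary thyroid nodule"]] <-
    lab[["Thyroid nodule(s)"]] && !lab[["Multiple thyroid nodules"]]
  lab[["Normal thyroid"]] <-
    lab[["Thyroid examination"]] && !any(lab[c(
      "Thyroid nodule(s)", "Altered thyroid echotexture", "Goitre",
      "Previous thyroid surgery")])
  lab
}

#' Generate a labelled synthetic ultrasound report corpus
#'
#' Deterministic for a fixed seed. Reports emulate UK neck/thyroid
#' ultrasound reports with embedded `Clinical history:` and `Findings:`
#' headers (a configurable fraction is headerless free text), findings
#' phrases with negations, BTA gradings, distractor pathology
#' (parotid/salivary/thyroglossal cysts, lymph nodes) and hedged/ambiguous
#' wording. Every report carries a complete ground-truth vector for the
#' fourteen packaged classes, consistent with its inserted phrases and the
#' derived-class and post-processing logic; reports containing phrases a
#' lexical strategy cannot resolve are flagged `ambiguous`.
#'
#' @param n number of reports (>= 0).
#' @param seed integer seed.
#' @param config named list overriding [synth_defaults()] entries (rates of
#'   negation, distractors, gradings, mean report length in words, ...).
#' @return A list with `reports` (data.frame `id`, `text`, `exam_date`,
#'   `age`, `exam_code`) and `labels` (data.frame `id`, one logical column
#'   per class, plus `ambiguous`).
#' @export
generate_corpus <- function(n, seed = 1L, config = list()) {
  stopifnot(n >= 0L)
  cfg <- utils::modifyList(synth_defaults(), config)
  if (isTRUE(cfg$force_solitary) && isTRUE(cfg$force_multiple)) {
    stop("contradictory config: force_solitary and force_multiple")
  }
  if (abs(sum(cfg$p_nodule) - 1) > 1e-8) {
    stop("p_nodule probabilities must sum to 1")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  banks <- synth_banks()
  classes <- thyroid_classes()
  reports <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    r <- synth_report(banks, cfg)
    id <- sprintf("SYN%05d", i)
    reports[[i]] <- data.frame(
      id = id, text = r$text,
      exam_date = as.Date("2015-01-01") + sample.int(1826, 1L) - 1L,
      age = sample(18:90, 1L),
      exam_code = sample(c("UNECK", "UTHYD", "UTHPY"), 1L),
      stringsAsFactors = FALSE)
    lab <- keys_to_labels(r$keys)
    labels[[i]] <- cbind(data.frame(id = id, stringsAsFactors = FALSE),
                         as.data.frame(as.list(lab), check.names = FALSE),
                         data.frame(ambiguous = r$ambiguous))
  }
  if (n == 0L) {
    reports_df <- data.frame(id = character(0), text = character(0),
                             exam_date = as.Date(character(0)),
                             age = integer(0), exam_code = character(0),
                             stringsAsFactors = FALSE)
    labels_df <- cbind(
      data.frame(id = character(0), stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(replicate(length(classes),
                                              logical(0), simplify = FALSE)),
                      classes),
      data.frame(ambiguous = logical(0)))
  } else {
    reports_df <- do.call(rbind, reports)
    labels_df <- do.call(rbind, labels)
  }
  rownames(reports_df) <- rownames(labels_df) <- NULL
  list(reports = reports_df, labels = labels_df)
}
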