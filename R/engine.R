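## ---------------------------------------------------------------------------
## Classification engine: apply a search strategy to preprocessed reports,
## compute derived classes and post-processing implications, and keep
## character-level evidence for every positive label.
## ---------------------------------------------------------------------------

EMPTY_EVIDENCE <- data.frame(
  section = character(0), start = integer(0), end = integer(0),
  text = character(0), negated = logical(0), trigger = character(0),
  trigger_start = integer(0), trigger_end = integer(0),
  stringsAsFactors = FALSE)

empty_evidence <- function() EMPTY_EVIDENCE

# Map sentence-level spans to raw-report coordinates using the sentence
# offset maps.
spans_to_raw <- function(spans, sentences, raw) {
  if (nrow(spans) == 0L) return(empty_evidence())
  n <- nrow(spans)
  section <- character(n); rs <- integer(n); re <- integer(n)
  ts <- rep(NA_integer_, n); te <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sen <- sentences[[spans$sentence[i]]]
    section[i] <- sen$section
    rs[i] <- sen$offsets[spans$start[i]]
    re[i] <- sen$offsets[spans$end[i]]
    if (!is.na(spans$trigger_start[i])) {
      ts[i] <- sen$offsets[spans$trigger_start[i]]
      te[i] <- sen$offsets[spans$trigger_end[i]]
    }
  }
  data.frame(section = section, start = rs, end = re,
             text = substr(rep(raw, n), rs, re), negated = spans$negated,
             trigger = spans$trigger, trigger_start = ts, trigger_end = te,
             stringsAsFactors = FALSE)
}

#' Classify a single preprocessed report
#'
#' Non-derived classes are evaluated over their configured sections (falling
#' back to the `body` section when none of them is present in the report),
#' with negated matches excluded from evidence. Derived classes are boolean
#' logic over already-computed labels. Post-processing implication rules
#' apply last, in file order, after which derived classes are re-evaluated
#' once (a fixpoint is asserted). Deterministic for fixed input.
#'
#' @param strategy a validated `radex_strategy`.
#' @param processed a `radex_processed` report (see [process_report()]).
#' @param lexicon negation lexicon; `NULL` disables negation globally.
#' @param and_scope `"section"` (default: AND children may match in
#'   different sentences of the class's section set) or `"sentence"` (the
#'   whole query must hold within one sentence).
#' @return An object of class `radex_result`: list with `id`, `labels`
#'   (named logical), `evidence` (named list of span tables in raw-text
#'   coordinates), `forced` (classes set positive by post-processing rules
#'   without textual evidence) and `raw`.
#' @export
classify_report <- function(strategy, processed,
                            lexicon = default_negation_lexicon(),
                            and_scope = c("section", "sentence")) {
  and_scope <- match.arg(and_scope)
  class_names <- strategy_classes(strategy)
  labels <- stats::setNames(rep(FALSE, length(class_names)), class_names)
  evidence <- stats::setNames(vector("list", length(class_names)), class_names)
  sections_vec <- vapply(processed$sentences, `[[`, character(1), "section")
  texts_all <- vapply(processed$sentences, `[[`, character(1), "text")
  sections_present <- unique(sections_vec)
  # negation contexts are per sentence and shared across all classes
  neg_cache <- vector("list", length(processed$sentences))
  neg_ctx <- function(gi) {
    if (is.null(neg_cache[[gi]])) {
      neg_cache[[gi]] <<- negation_context(processed$sentences[[gi]]$text,
                                           lexicon)
    }
    neg_cache[[gi]]
  }

  eval_class <- function(cl) {
    secs <- intersect(cl$sections, sections_present)
    if (!length(secs)) secs <- intersect("body", sections_present)
    idx <- which(sections_vec %in% secs)
    sens <- processed$sentences[idx]
    texts <- texts_all[idx]
    negator <- NULL
    if (!is.null(lexicon) && cl$negation) {
      negator <- function(si, start, end) {
        flags_with_context(neg_ctx(idx[si]), start, end)
      }
    }
    resolver <- function(name) {
      if (!name %in% names(labels)) return(NA)
      labels[[name]]
    }
    if (length(texts) == 0L) {
      res <- eval_query_sentences(cl$query, character(0), resolver, negator)
      return(list(present = res$present, evidence = empty_evidence()))
    }
    if (and_scope == "sentence" && !cl$derived) {
      present <- FALSE
      spans <- empty_spans()
      for (si in seq_along(texts)) {
        neg_i <- if (is.null(negator)) NULL else {
          function(k, start, end) negator(si, start, end)
        }
        r <- eval_query_sentences(cl$query, texts[si], resolver, neg_i)
        if (r$present) {
          present <- TRUE
          if (nrow(r$spans)) {
            r$spans$sentence <- si
            spans <- rbind(spans, r$spans)
          }
        }
      }
      res <- list(present = present, spans = spans)
    } else {
      res <- eval_query_sentences(cl$query, texts, resolver, negator)
    }
    ev <- spans_to_raw(res$spans, sens, processed$raw)
    list(present = res$present, evidence = ev)
  }

  for (cl in strategy$classes) {
    if (is.null(cl$query)) {
      stop("class '", cl$name, "' has an invalid query; run validate_strategy()")
    }
    cl$query <- compile_query_tree(cl$query)
    r <- eval_class(cl)
    labels[[cl$name]] <- r$present
    evidence[[cl$name]] <- r$evidence
  }

  forced <- character(0)
  apply_post <- function() {
    for (rule in strategy$post_rules) {
      if (isTRUE(labels[[rule$if_class]]) &&
          !identical(labels[[rule$then_class]], rule$set_to)) {
        labels[[rule$then_class]] <<- rule$set_to
        if (rule$set_to) forced <<- union(forced, rule$then_class)
      }
    }
  }
  rederive <- function() {
    for (cl in strategy$classes) {
      if (cl$derived) {
        r <- eval_class(cl)
        labels[[cl$name]] <<- r$present
        evidence[[cl$name]] <<- r$evidence
      }
    }
  }
  if (length(strategy$post_rules)) {
    apply_post()
    rederive()
    # post-rules and derived definitions must agree after one re-derivation
    before <- labels
    apply_post()
    rederive()
    stopifnot(identical(before, labels))
  }

  structure(list(id = processed$id, labels = labels, evidence = evidence,
                 forced = forced, raw = processed$raw),
            class = "radex_result")
}

#' @export
print.radex_result <- function(x, ...) {
  pos <- names(x$labels)[x$labels]
  cat(sprintf("<radex result %s> positive: %s\n", x$id,
              if (length(pos)) paste(pos, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Classify a corpus of reports
#'
#' Preprocesses and classifies each report in order. Duplicate report ids
#' are an error before any processing starts; individual report failures are
#' logged and recorded, never aborting the batch.
#'
#' @param strategy a `radex_strategy`; validated before the run.
#' @param reports corpus data.frame with `id` and `text` columns.
#' @param lexicon negation lexicon; `NULL` disables negation.
#' @param headers section headers (defaults to the strategy's `headers`).
#' @param remove_stopwords passed to [standardise()].
#' @param and_scope see [classify_report()].
#' @param verbose emit a per-run log with per-class positive counts.
#' @return An object of class `radex_results`: a list of `radex_result`
#'   (order preserved), with failed reports carrying an `error` field.
#' @export
classify_corpus <- function(strategy, reports,
                            lexicon = default_negation_lexicon(),
                            headers = NULL, remove_stopwords = FALSE,
                            and_scope = "section", verbose = FALSE) {
  stopifnot(is.data.frame(reports), all(c("id", "text") %in% names(reports)))
  if (anyDuplicated(reports$id)) {
    stop("duplicate report ids: ",
         paste(unique(reports$id[duplicated(reports$id)]), collapse = ", "))
  }
  errs <- validate_strategy(strategy)
  if (length(errs)) {
    stop("strategy is invalid: ",
         paste(vapply(errs, conditionMessage, character(1)), collapse = "; "))
  }
  headers <- headers %||% strategy$headers
  t0 <- proc.time()[["elapsed"]]
  results <- vector("list", nrow(reports))
  n_failed <- 0L
  for (i in seq_len(nrow(reports))) {
    results[[i]] <- tryCatch({
      proc <- process_report(reports[i, , drop = FALSE], headers,
                             remove_stopwords = remove_stopwords)
      classify_report(strategy, proc, lexicon, and_scope = and_scope)
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      message(sprintf("classify_corpus: report %s failed: %s",
                      reports$id[i], conditionMessage(e)))
      structure(list(id = reports$id[i],
                     labels = stats::setNames(
                       rep(NA, length(strategy_classes(strategy))),
                       strategy_classes(strategy)),
                     evidence = list(), forced = character(0),
                     raw = reports$text[i],
                     error = conditionMessage(e)),
                class = "radex_result")
    })
  }
  out <- structure(results, class = "radex_results")
  attr(out, "classes") <- strategy_classes(strategy)
  attr(out, "elapsed") <- proc.time()[["elapsed"]] - t0
  attr(out, "n_failed") <- n_failed
  if (verbose) {
    lm <- labels_matrix(out)
    counts <- colSums(lm[-1] == TRUE, na.rm = TRUE)
    message(sprintf("classified %d report(s) in %.2fs (%d failed)",
                    nrow(reports), attr(out, "elapsed"), n_failed))
    for (nm in names(counts)) {
      message(sprintf("  %-28s %d positive", nm, counts[[nm]]))
    }
  }
  out
}

#' @export
print.radex_results <- function(x, ...) {
  cat(sprintf("<radex results: %d report(s), %d class(es)>\n",
              length(x), length(attr(x, "classes"))))
  invisible(x)
}

#' Label matrix of classification results
#'
#' @param results a `radex_results` object.
#' @return data.frame with `id` plus one logical column per class.
#' @export
labels_matrix <- function(results) {
  classes <- attr(results, "classes")
  rows <- lapply(results, function(r) {
    c(list(id = r$id), as.list(r$labels[classes]))
  })
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Write classification results
#'
#' One row per report with a boolean column per class plus a JSON `evidence`
#' column (non-negated spans only).
#'
#' @param results a `radex_results`.
#' @param path output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_labels <- function(results, path) {
  df <- labels_matrix(results)
  df$evidence <- vapply(seq_along(results), function(i) {
    ev <- results[[i]]$evidence
    ev <- lapply(ev, function(e) {
      if (is.null(e) || nrow(e) == 0L) return(NULL)
      e[!e$negated, c("section", "start", "end", "text"), drop = FALSE]
    })
    ev <- ev[!vapply(ev, is.null, logical(1))]
    as.character(jsonlite::toJSON(ev, dataframe = "rows", auto_unbox = TRUE))
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}

#' Flag disagreements with reference labels
#'
#' Compares predicted labels with a reference-standard table and returns one
#' record per disagreeing (report, class) pair, for manual review during
#' iterative strategy refinement. False positives carry the offending
#' evidence spans; false negatives carry the report text for review.
#' Reports or classes missing from the reference are excluded and logged.
#'
#' @param results a `radex_results`.
#' @param reference data.frame with `id` plus one logical column per class.
#' @return data.frame with columns `id`, `class`, `kind` (`"FP"`/`"FN"`) and
#'   `evidence` (character).
#' @export
flag_discrepancies <- function(results, reference) {
  stopifnot(is.data.frame(reference), "id" %in% names(reference))
  classes <- intersect(attr(results, "classes"), setdiff(names(reference), "id"))
  missing_cls <- setdiff(attr(results, "classes"), names(reference))
  if (length(missing_cls)) {
    message("flag_discrepancies: class(es) without reference labels skipped: ",
            paste(missing_cls, collapse = ", "))
  }
  out <- data.frame(id = character(0), class = character(0),
                    kind = character(0), evidence = character(0),
                    stringsAsFactors = FALSE)
  skipped <- character(0)
  for (r in results) {
    ri <- match(r$id, reference$id)
    if (is.na(ri)) {
      skipped <- c(skipped, r$id)
      next
    }
    for (cls in classes) {
      ref <- isTRUE(as.logical(reference[[cls]][ri]))
      pred <- isTRUE(r$labels[[cls]])
      if (is.na(reference[[cls]][ri])) {
        skipped <- c(skipped, paste0(r$id, "/", cls))
        next
      }
      if (pred == ref) next
      if (pred && !ref) {
        ev <- r$evidence[[cls]]
        ev_txt <- if (!is.null(ev) && nrow(ev)) {
          paste(sprintf("[%d,%d] %s", ev$start[!ev$negated],
                        ev$end[!ev$negated], ev$text[!ev$negated]),
                collapse = "; ")
        } else if (cls %in% r$forced) {
          "(set by post-processing rule)"
        } else {
          "(derived class)"
        }
        out <- rbind(out, data.frame(id = r$id, class = cls, kind = "FP",
                                     evidence = ev_txt,
                                     stringsAsFactors = FALSE))
      } else {
        out <- rbind(out, data.frame(id = r$id, class = cls, kind = "FN",
                                     evidence = r$raw,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (length(skipped)) {
    message("flag_discrepancies: missing reference label(s) for: ",
            paste(utils::head(unique(skipped), 5L), collapse = ", "))
  }
  out
}
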