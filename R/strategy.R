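## ---------------------------------------------------------------------------
## Search strategies: an ordered set of named classes, each defined by a
## query expression, target sections, and a derived flag, plus a list of
## post-processing implication rules. Loaded from YAML.
## ---------------------------------------------------------------------------

#' Read a search strategy from YAML
#'
#' A strategy file maps ordered class names to query expressions. Layout:
#' \preformatted{
#' name: my strategy
#' headers: [clinical history, findings]
#' classes:
#'   - name: Thyroid examination
#'     query: thyroid*
#'     sections: [findings]
#'     negation: false
#'   - name: Solitary thyroid nodule
#'     query: '"Thyroid nodule(s)" & NOT "Multiple thyroid nodules"'
#'     derived: true
#' post_processing:
#'   - {if: BTA U2, then: "Thyroid nodule(s)", set_to: true}
#' }
#' Classes default to `sections: [body]`, `derived: false` and
#' `negation: true`. Derived classes are written in the same query language
#' using double-quoted references to earlier classes.
#'
#' @param path YAML file path.
#' @return An object of class `radex_strategy`.
#' @seealso [thyroid_strategy()], [validate_strategy()]
#' @export
read_strategy <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$classes) || !length(raw$classes)) {
    stop("strategy has no classes")
  }
  classes <- lapply(raw$classes, function(cl) {
    stopifnot(!is.null(cl$name), !is.null(cl$query))
    list(name = as.character(cl$name),
         query_text = as.character(cl$query),
         query = tryCatch(compile_query_tree(parse_query(cl$query)),
                          radex_parse_error = function(e) NULL),
         sections = tolower(as.character(cl$sections %||% "body")),
         derived = isTRUE(cl$derived),
         negation = !isFALSE(cl$negation))
  })
  post <- lapply(raw$post_processing %||% list(), function(r) {
    stopifnot(!is.null(r$`if`), !is.null(r$then))
    list(if_class = as.character(r$`if`),
         then_class = as.character(r$then),
         set_to = isTRUE(r$set_to %||% TRUE))
  })
  structure(list(name = raw$name %||% basename(path),
                 headers = tolower(as.character(raw$headers %||% character(0))),
                 classes = classes, post_rules = post,
                 path = path),
            class = "radex_strategy")
}

#' Packaged neck/thyroid ultrasound search strategy
#'
#' Loads the packaged strategy classifying neck and thyroid ultrasound
#' reports for fourteen clinical features: thyroid and lymph node
#' examination, thyroid nodule(s), multiple/solitary nodules, altered
#' echotexture, goitre, previous thyroid surgery, BTA U1-U5 gradings, and
#' normal thyroid. Solitary nodule and normal thyroid are derived classes;
#' post-processing rules force nodule presence when a BTA U2-U5 grading or
#' multiple nodules are found.
#'
#' @return A `radex_strategy`.
#' @export
thyroid_strategy <- function() {
  read_strategy(system.file("extdata", "thyroid_bta.yaml", package = "radex"))
}

#' Class names of a strategy
#' @param strategy a `radex_strategy`.
#' @return Character vector in definition order.
#' @export
strategy_classes <- function(strategy) {
  vapply(strategy$classes, `[[`, character(1), "name")
}

#' @export
print.radex_strategy <- function(x, ...) {
  cat(sprintf("<radex strategy '%s': %d classes, %d post-processing rule(s)>\n",
              x$name, length(x$classes), length(x$post_rules)))
  for (cl in x$classes) {
    cat(sprintf("  %s%s: %s\n", cl$name,
                if (cl$derived) " [derived]" else "",
                substr(cl$query_text, 1, 60)))
  }
  invisible(x)
}

#' Validate a search strategy
#'
#' Checks that every class query parses, that every double-quoted class
#' reference resolves to a class defined *earlier* in the same strategy
#' (which also rules out cyclic derived-class definitions), and that
#' post-processing rules reference defined classes. Errors are accumulated
#' and returned, not raised.
#'
#' @param strategy a `radex_strategy`.
#' @return A list of `radex_parse_error` conditions, each carrying the
#'   offending class name; empty when the strategy is valid.
#' @export
validate_strategy <- function(strategy) {
  errors <- list()
  seen <- character(0)
  all_names <- strategy_classes(strategy)
  if (anyDuplicated(all_names)) {
    dup <- unique(all_names[duplicated(all_names)])
    errors[[length(errors) + 1L]] <- parse_error(
      "unknown_class_reference", 1L,
      paste("duplicated class name(s):", paste(dup, collapse = ", ")))
  }
  for (cl in strategy$classes) {
    ast <- tryCatch(parse_query(cl$query_text), radex_parse_error = function(e) e)
    if (inherits(ast, "radex_parse_error")) {
      ast$class_name <- cl$name
      errors[[length(errors) + 1L]] <- ast
    } else {
      refs <- query_classrefs(ast)
      bad <- setdiff(refs, seen)
      for (b in bad) {
        msg <- if (b %in% all_names) {
          sprintf("class '%s' references '%s', which is not defined earlier (cyclic or forward reference)",
                  cl$name, b)
        } else {
          sprintf("class '%s' references unknown class '%s'", cl$name, b)
        }
        e <- parse_error("unknown_class_reference", 1L, msg, cl$name)
        errors[[length(errors) + 1L]] <- e
      }
    }
    seen <- c(seen, cl$name)
  }
  for (r in strategy$post_rules) {
    for (nm in c(r$if_class, r$then_class)) {
      if (!nm %in% all_names) {
        errors[[length(errors) + 1L]] <- parse_error(
          "unknown_class_reference", 1L,
          sprintf("post-processing rule references unknown class '%s'", nm))
      }
    }
  }
  errors
}
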