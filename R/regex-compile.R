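## ---------------------------------------------------------------------------
## Compilation of query nodes to PCRE patterns.
##
## Word characters are letters and digits; hyphen, slash and all other
## punctuation act as word separators (text standardisation maps them to
## spaces). Word boundaries are expressed as lookarounds on the word-character
## class so that underscores never count as word characters.
## ---------------------------------------------------------------------------

WORD_CLASS <- "[a-z0-9]"
NONWORD_CLASS <- "[^a-z0-9]"
BOUND_L <- "(?<![a-z0-9])"
BOUND_R <- "(?![a-z0-9])"

# One atom ('nodul*', 'wom?n', 'u2') -> regex body without boundaries.
atom_regex <- function(atom) {
  chars <- strsplit(atom, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    if (ch == "*") {
      paste0(WORD_CLASS, "*")
    } else if (ch == "?") {
      paste0(WORD_CLASS, "?")
    } else if (ch %in% c(".", "\\", "|", "(", ")", "[", "]", "{", "}",
                         "^", "$", "+")) {
      paste0("\\", tolower(ch))   # escape regex metacharacters
    } else {
      tolower(ch)
    }
  }, character(1)), collapse = "")
}

# Term pattern body: atoms wrapped in word boundaries, adjacent atoms joined
# by exactly one run of non-word characters.
term_regex <- function(atoms) {
  paste(vapply(atoms, function(a) {
    paste0(BOUND_L, atom_regex(a), BOUND_R)
  }, character(1)), collapse = paste0(NONWORD_CLASS, "+"))
}

new_compiled <- function(pattern, node) {
  structure(list(pattern = pattern, source = node),
            class = "radex_compiled")
}

#' @export
print.radex_compiled <- function(x, ...) {
  cat("<compiled pattern> ", x$pattern, "\n", sep = "")
  invisible(x)
}

#' Compile a term pattern to a regular expression
#'
#' `*` compiles to zero-or-more word characters and `?` to zero-or-one word
#' character; literals are escaped; every atom is wrapped in word boundaries.
#' Multi-atom phrases compile to atoms joined by exactly one non-word
#' character run, so `lymph node?` matches "lymph node" and "lymph nodes"
#' as an adjacent phrase. Matching is case-insensitive (patterns are applied
#' to lowercased, standardised text).
#'
#' @param term a `radex_query` term node, or a character expression that
#'   parses to one.
#' @return A `radex_compiled` object with fields `pattern` and `source`.
#' @examples
#' compile_term("thyr*")$pattern
#' @export
compile_term <- function(term) {
  if (is.character(term)) term <- parse_query(term)
  stopifnot(identical(term$type, "term"))
  new_compiled(term_regex(term$atoms), term)
}

#' Compile a proximity node to a regular expression
#'
#' `THEN/X` compiles to the left pattern, a lazily quantified group of 0 to X
#' intervening words, then the right pattern. `NEAR/X` is the alternation of
#' both orders, making it order-independent.
#'
#' @param node a `radex_query` node of type `near` or `then` (or an
#'   expression parsing to one).
#' @return A `radex_compiled` object.
#' @examples
#' compile_proximity("thyroid NEAR/2 nodules")$pattern
#' @export
compile_proximity <- function(node) {
  if (is.character(node)) node <- parse_query(node)
  stopifnot(node$type %in% c("near", "then"))
  new_compiled(proximity_regex(node), node)
}

# Directed phrase-gap-phrase body.
then_regex <- function(left_atoms, right_atoms, gap) {
  sprintf("%s(?:%s+%s+){0,%d}?%s+%s",
          term_regex(left_atoms),
          NONWORD_CLASS, WORD_CLASS, gap,
          NONWORD_CLASS,
          term_regex(right_atoms))
}

proximity_regex <- function(node) {
  if (node$type == "then") {
    then_regex(node$left$atoms, node$right$atoms, node$gap)
  } else {
    paste0("(?:",
           then_regex(node$left$atoms, node$right$atoms, node$gap),
           "|",
           then_regex(node$right$atoms, node$left$atoms, node$gap),
           ")")
  }
}

# Compile any leaf (term/near/then) to its pattern string.
leaf_regex <- function(node) {
  switch(node$type,
    term = term_regex(node$atoms),
    near = ,
    then = proximity_regex(node),
    stop("not a leaf node: ", node$type)
  )
}

## ---------------------------------------------------------------------------
## Evaluation
## ---------------------------------------------------------------------------

# All leftmost non-overlapping matches of a compiled pattern in one string.
# Returns a data.frame with 1-based inclusive start/end and the matched text.
regex_spans <- function(pattern, text) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len - 1L,
             text = substring(text, start, start + len - 1L),
             stringsAsFactors = FALSE)
}

EMPTY_SPANS_DF <- data.frame(
  sentence = integer(0), start = integer(0), end = integer(0),
  text = character(0), negated = logical(0), trigger = character(0),
  trigger_start = integer(0), trigger_end = integer(0),
  stringsAsFactors = FALSE)

empty_spans <- function() EMPTY_SPANS_DF

## Internal span representation: a list of parallel column vectors
## (sentence, start, end, text, negated, trigger, trigger_start,
## trigger_end). data.frames are only built at the API boundary; building
## them inside the recursive evaluator dominates runtime otherwise.

span_cols_empty <- function() {
  list(sentence = integer(0), start = integer(0), end = integer(0),
       text = character(0), negated = logical(0),
       trigger = character(0), trigger_start = integer(0),
       trigger_end = integer(0))
}

span_cols_bind <- function(parts) {
  if (!length(parts)) return(span_cols_empty())
  if (length(parts) == 1L) return(parts[[1]])
  out <- span_cols_empty()
  for (nm in names(out)) {
    out[[nm]] <- unlist(lapply(parts, `[[`, nm), use.names = FALSE)
  }
  out
}

span_cols_to_df <- function(cols) {
  if (!length(cols$start)) return(EMPTY_SPANS_DF)
  data.frame(cols, stringsAsFactors = FALSE)
}

# Core recursive evaluator over a vector of standardised sentences.
#   resolver: function(name) -> logical, for classref nodes
#   negator:  function(sentence_index, start, end) -> list(negated, trigger,
#             trigger_start, trigger_end)
# Presence semantics: a leaf is present iff it has at least one non-negated
# match in any sentence; AND requires all children present anywhere in the
# sentence set (section scope); NOT contributes no spans.
eval_query_cols <- function(node, sentences, resolver = NULL,
                            negator = NULL) {
  switch(node$type,
    term = ,
    near = ,
    then = {
      pat <- node$pattern %||% leaf_regex(node)
      parts <- list()
      if (length(sentences)) {
        ms <- gregexpr(pat, sentences, perl = TRUE)
        for (si in seq_along(sentences)) {
          m <- ms[[si]]
          if (m[1] == -1L) next
          start <- as.integer(m)
          end <- start + attr(m, "match.length") - 1L
          k <- length(start)
          if (is.null(negator)) {
            neg <- list(negated = rep(FALSE, k),
                        trigger = rep(NA_character_, k),
                        trigger_start = rep(NA_integer_, k),
                        trigger_end = rep(NA_integer_, k))
          } else {
            neg <- negator(si, start, end)
          }
          parts[[length(parts) + 1L]] <- list(
            sentence = rep(si, k), start = start, end = end,
            text = substring(sentences[[si]], start, end),
            negated = neg$negated, trigger = neg$trigger,
            trigger_start = neg$trigger_start, trigger_end = neg$trigger_end)
        }
      }
      spans <- span_cols_bind(parts)
      list(present = any(!spans$negated), spans = spans)
    },
    classref = {
      if (is.null(resolver)) {
        stop("class reference \"", node$name,
             "\" cannot be resolved: no resolver supplied")
      }
      val <- resolver(node$name)
      if (is.null(val) || is.na(val)) {
        stop("class reference \"", node$name,
             "\" does not resolve to an earlier class")
      }
      list(present = isTRUE(val), spans = span_cols_empty())
    },
    and = {
      parts <- lapply(node$children, eval_query_cols, sentences,
                      resolver, negator)
      present <- all(vapply(parts, `[[`, logical(1), "present"))
      spans <- if (present) {
        span_cols_bind(lapply(parts, `[[`, "spans"))
      } else {
        span_cols_empty()
      }
      list(present = present, spans = spans)
    },
    or = {
      parts <- lapply(node$children, eval_query_cols, sentences,
                      resolver, negator)
      present <- any(vapply(parts, `[[`, logical(1), "present"))
      spans <- span_cols_bind(lapply(parts, `[[`, "spans"))
      list(present = present, spans = spans)
    },
    not = {
      part <- eval_query_cols(node$child, sentences, resolver, negator)
      list(present = !part$present, spans = span_cols_empty())
    },
    stop("unknown node type: ", node$type)
  )
}

eval_query_sentences <- function(node, sentences, resolver = NULL,
                                 negator = NULL) {
  res <- eval_query_cols(node, sentences, resolver, negator)
  list(present = res$present, spans = span_cols_to_df(res$spans))
}

#' Evaluate a query over standardised text
#'
#' Recursively evaluates a query AST over one or more standardised sentences.
#' Term and proximity leaves are present when the compiled pattern has at
#' least one (non-negated, if a negation lexicon is supplied) match; `OR`
#' takes the union of children, `AND` requires all children present anywhere
#' in the supplied text (section scope), and `NOT` inverts presence and
#' contributes no spans. Deterministic for fixed input.
#'
#' @param node a `radex_query` node or character expression.
#' @param text a character vector of standardised sentences (a single string
#'   is treated as one sentence).
#' @param resolver optional `function(name)` returning the boolean label of a
#'   previously computed class, for derived-class references.
#' @param lexicon optional [negation_lexicon()]; when supplied, negated
#'   matches are flagged and excluded from presence.
#' @return A list with `present` (logical) and `spans`, a data.frame with
#'   columns `sentence`, `start`, `end`, `text`, `negated`, `trigger`
#'   (1-based inclusive character offsets into the sentence).
#' @examples
#' evaluate_query("node? EXCEPT lymph node?", "lymph nodes are normal")$present
#' @export
evaluate_query <- function(node, text, resolver = NULL, lexicon = NULL) {
  if (is.character(node)) node <- parse_query(node)
  negator <- NULL
  if (!is.null(lexicon)) {
    negator <- function(si, start, end) {
      detect_negation_flags(text[[si]], start, end, lexicon)
    }
  }
  eval_query_sentences(node, text, resolver, negator)
}

#' Export compiled class patterns for audit
#'
#' Compiles every term/proximity leaf of each non-derived class of a strategy
#' and writes them as plain-text regular expressions with provenance
#' comments, one block per class.
#'
#' @param strategy a `radex_strategy`.
#' @param path optional output file; when `NULL` the text is returned.
#' @return Invisibly, the character vector of lines.
#' @export
export_patterns <- function(strategy, path = NULL) {
  lines <- character(0)
  for (cls in strategy$classes) {
    lines <- c(lines, sprintf("# class: %s", cls$name),
               sprintf("# query: %s", deparse_query(cls$query)))
    if (cls$derived) {
      lines <- c(lines, "# derived class: boolean logic over earlier labels", "")
      next
    }
    leaves <- collect_leaves(cls$query)
    for (lf in leaves) {
      lines <- c(lines,
                 sprintf("# leaf: %s", deparse_query(lf)),
                 leaf_regex(lf))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# Attach compiled patterns to every leaf of a query tree so repeated
# evaluation does not rebuild pattern strings.
compile_query_tree <- function(node) {
  if (is.null(node)) return(NULL)
  switch(node$type,
    term = ,
    near = ,
    then = {
      node$pattern <- leaf_regex(node)
      node
    },
    not = {
      node$child <- compile_query_tree(node$child)
      node
    },
    and = ,
    or = {
      node$children <- lapply(node$children, compile_query_tree)
      node
    },
    node
  )
}

collect_leaves <- function(node) {
  switch(node$type,
    term = ,
    near = ,
    then = list(node),
    classref = list(),
    not = collect_leaves(node$child),
    and = ,
    or = do.call(c, lapply(node$children, collect_leaves)),
    list()
  )
}
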