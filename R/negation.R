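## ---------------------------------------------------------------------------
## NegEx-style negation detection: pre- and post-negation trigger phrases
## with a bounded in-sentence scope, pseudo-triggers that never negate, and
## terminator tokens that break scope.
## ---------------------------------------------------------------------------

#' Construct a negation lexicon
#'
#' @param pre pre-negation trigger phrases (negate targets after them).
#' @param post post-negation trigger phrases (negate targets before them).
#' @param pseudo phrases that look like triggers but never negate
#'   (checked before real triggers, e.g. "not only").
#' @param terminators scope-breaking words ("but", "however").
#' @param uncertainty hypothetical/uncertainty phrases; matches inside their
#'   scope are flagged but never suppressed.
#' @param scope maximum number of tokens between trigger and target.
#' @return An object of class `radex_lexicon`.
#' @export
negation_lexicon <- function(pre = character(0), post = character(0),
                             pseudo = character(0),
                             terminators = character(0),
                             uncertainty = character(0), scope = 5L) {
  scope <- as.integer(scope)
  stopifnot(scope >= 1L)
  split_words <- function(x) strsplit(tolower(x), " +")
  structure(list(pre = tolower(pre), post = tolower(post),
                 pseudo = tolower(pseudo), term = tolower(terminators),
                 unc = tolower(uncertainty), scope = scope,
                 words = list(pre = split_words(pre), post = split_words(post),
                              pseudo = split_words(pseudo),
                              term = split_words(terminators),
                              unc = split_words(uncertainty))),
            class = "radex_lexicon")
}

#' @export
print.radex_lexicon <- function(x, ...) {
  cat(sprintf(
    "<negation lexicon: %d pre, %d post, %d pseudo, %d terminator, %d uncertainty; scope %d>\n",
    length(x$pre), length(x$post), length(x$pseudo), length(x$term),
    length(x$unc), x$scope))
  invisible(x)
}

#' Read a negation lexicon from a trigger file
#'
#' The file holds one trigger per line as `phrase<TAB>TAG` with tags `PRE`,
#' `POST`, `PSEUDO`, `TERM` or `UNC`; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path trigger file; defaults to the packaged lexicon seeded with
#'   the standard NegEx trigger set.
#' @param scope maximum tokens between trigger and target.
#' @return A `radex_lexicon`.
#' @export
read_negation_lexicon <- function(path = NULL, scope = 5L) {
  if (is.null(path)) {
    path <- system.file("extdata", "negex_triggers.txt", package = "radex")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed lexicon line(s): ",
                     paste(lines[bad], collapse = "; "))
  phrase <- tolower(trimws(vapply(parts, `[[`, character(1), 1L)))
  tag <- toupper(trimws(vapply(parts, `[[`, character(1), 2L)))
  if (!all(tag %in% c("PRE", "POST", "PSEUDO", "TERM", "UNC"))) {
    stop("lexicon tags must be PRE, POST, PSEUDO, TERM or UNC")
  }
  negation_lexicon(pre = phrase[tag == "PRE"], post = phrase[tag == "POST"],
                   pseudo = phrase[tag == "PSEUDO"],
                   terminators = phrase[tag == "TERM"],
                   uncertainty = phrase[tag == "UNC"], scope = scope)
}

#' Default packaged negation lexicon
#'
#' @param scope maximum tokens between trigger and target (the classic NegEx
#'   convention of 5 by default).
#' @return A `radex_lexicon`.
#' @export
default_negation_lexicon <- function(scope = 5L) {
  read_negation_lexicon(NULL, scope = scope)
}

# Tokenise a standardised sentence: tokens are runs of non-space characters.
# Returns data.frame(token, start, end) with 1-based inclusive offsets.
sentence_tokens <- function(sentence) {
  m <- gregexpr("[^ ]+", sentence)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  data.frame(token = substring(sentence, start, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

# Locate trigger-phrase instances as token ranges. Longest phrase wins on
# overlap; pseudo-triggers compete so that they mask the real triggers they
# contain.
trigger_instances <- function(tokens, lexicon) {
  tok <- tokens$token
  n_tok <- length(tok)
  word_lists <- lexicon$words %||% list(
    pre = strsplit(lexicon$pre, " +"), post = strsplit(lexicon$post, " +"),
    pseudo = strsplit(lexicon$pseudo, " +"),
    term = strsplit(lexicon$term, " +"), unc = strsplit(lexicon$unc, " +"))
  find <- function(phrases, words_list, tag) {
    out <- list()
    for (pi in seq_along(phrases)) {
      words <- words_list[[pi]]
      k <- length(words)
      if (k == 0L || n_tok < k) next
      hits <- which(tok == words[1])
      hits <- hits[hits <= n_tok - k + 1L]
      for (s in hits) {
        if (k == 1L || all(tok[s:(s + k - 1L)] == words)) {
          out[[length(out) + 1L]] <- list(
            start_tok = s, end_tok = s + k - 1L, tag = tag,
            phrase = phrases[pi], nwords = k)
        }
      }
    }
    out
  }
  inst <- c(find(lexicon$pseudo, word_lists$pseudo, "PSEUDO"),
            find(lexicon$pre, word_lists$pre, "PRE"),
            find(lexicon$post, word_lists$post, "POST"),
            find(lexicon$term, word_lists$term, "TERM"),
            find(lexicon$unc, word_lists$unc, "UNC"))
  if (!length(inst)) return(list())
  # longest first (pseudo listed first breaks ties in its favour)
  ord <- order(-vapply(inst, `[[`, integer(1), "nwords"))
  inst <- inst[ord]
  accepted <- list()
  covered <- integer(0)
  for (x in inst) {
    rng <- x$start_tok:x$end_tok
    if (any(rng %in% covered)) next
    accepted[[length(accepted) + 1L]] <- x
    covered <- c(covered, rng)
  }
  accepted
}

# Precompute the per-sentence negation context (tokens and accepted trigger
# instances) so that it can be shared across all leaves of a strategy.
negation_context <- function(sentence, lexicon) {
  tokens <- sentence_tokens(sentence)
  inst <- if (nrow(tokens)) trigger_instances(tokens, lexicon) else list()
  term_toks <- unlist(lapply(
    inst[vapply(inst, `[[`, character(1), "tag") == "TERM"],
    function(x) x$start_tok:x$end_tok))
  list(tokens = tokens, inst = inst,
       term_toks = term_toks %||% integer(0), scope = lexicon$scope)
}

# Internal: negation flags for leaf spans of one sentence, given as
# parallel start/end offset vectors.
detect_negation_flags <- function(sentence, start, end, lexicon) {
  flags_with_context(negation_context(sentence, lexicon), start, end)
}

flags_with_context <- function(ctx, start, end) {
  n <- length(start)
  res <- list(negated = rep(FALSE, n), trigger = rep(NA_character_, n),
              trigger_start = rep(NA_integer_, n),
              trigger_end = rep(NA_integer_, n),
              uncertain = rep(FALSE, n))
  if (n == 0L) return(res)
  tokens <- ctx$tokens
  inst <- ctx$inst
  term_toks <- ctx$term_toks
  lexicon <- list(scope = ctx$scope)
  if (nrow(tokens) == 0L || !length(inst)) return(res)
  for (i in seq_len(n)) {
    # token range of the span
    s_tok <- which(tokens$end >= start[i])[1]
    e_tok <- rev(which(tokens$start <= end[i]))[1]
    if (is.na(s_tok) || is.na(e_tok)) next
    best <- NULL
    best_dist <- Inf
    for (x in inst) {
      if (x$tag == "PRE" && x$end_tok < s_tok) {
        dist <- s_tok - x$end_tok
        between <- if (x$end_tok + 1L <= s_tok - 1L) (x$end_tok + 1L):(s_tok - 1L) else integer(0)
      } else if (x$tag == "POST" && x$start_tok > e_tok) {
        dist <- x$start_tok - e_tok
        between <- if (e_tok + 1L <= x$start_tok - 1L) (e_tok + 1L):(x$start_tok - 1L) else integer(0)
      } else if (x$tag == "UNC" && x$end_tok < s_tok) {
        if (s_tok - x$end_tok <= lexicon$scope &&
            !any((if (x$end_tok + 1L <= s_tok - 1L) (x$end_tok + 1L):(s_tok - 1L) else integer(0)) %in% term_toks)) {
          res$uncertain[i] <- TRUE
        }
        next
      } else {
        next
      }
      if (dist > lexicon$scope) next
      if (any(between %in% term_toks)) next
      if (dist < best_dist) {
        best <- x
        best_dist <- dist
      }
    }
    if (!is.null(best)) {
      res$negated[i] <- TRUE
      res$trigger[i] <- best$phrase
      res$trigger_start[i] <- tokens$start[best$start_tok]
      res$trigger_end[i] <- tokens$end[best$end_tok]
    }
  }
  res
}

#' Detect negated matches in a standardised sentence
#'
#' A span is negated iff a pre-negation trigger occurs within `scope` tokens
#' before it, or a post-negation trigger within `scope` tokens after it, with
#' no terminator in between. Pseudo-triggers never negate and mask the real
#' triggers they contain ("no abnormal" is reported over "no" when both
#' match, because the longest trigger wins). Negation never crosses sentence
#' boundaries because detection operates on a single sentence.
#'
#' @param sentence a standardised sentence (see [standardise()]).
#' @param spans a data.frame with `start`/`end` columns (1-based inclusive
#'   offsets into `sentence`), e.g. from [evaluate_query()].
#' @param lexicon a [negation_lexicon()]; defaults to the packaged set.
#' @return `spans` with added logical `negated`, character `trigger`
#'   (negating phrase or `NA`) and logical `uncertain` columns.
#' @examples
#' lex <- negation_lexicon(pre = c("no", "no abnormal"))
#' sp <- evaluate_query("thyroid nodules", "there are no thyroid nodules")$spans
#' detect_negation("there are no thyroid nodules", sp, lex)
#' @export
detect_negation <- function(sentence, spans, lexicon = default_negation_lexicon()) {
  stopifnot(is.data.frame(spans), all(c("start", "end") %in% names(spans)))
  if (nrow(spans) > 0L) {
    stopifnot(all(spans$start >= 1L), all(spans$end <= nchar(sentence)))
  }
  flags <- detect_negation_flags(sentence, spans$start, spans$end, lexicon)
  spans$negated <- flags$negated
  spans$trigger <- flags$trigger
  spans$trigger_start <- flags$trigger_start
  spans$trigger_end <- flags$trigger_end
  spans$uncertain <- flags$uncertain
  spans
}
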