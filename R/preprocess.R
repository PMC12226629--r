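## ---------------------------------------------------------------------------
## Corpus reading/writing, filtering, sectioning and text standardisation.
##
## Coordinate convention: all spans and offset maps are 1-based inclusive
## character positions on the RAW report text, so evidence highlighting never
## drifts after lowercasing, punctuation mapping or whitespace collapsing.
## ---------------------------------------------------------------------------

#' Read or write a report corpus
#'
#' Corpora are tables with columns `id` (pseudoidentifier, required), `text`
#' (raw report, required) and optional metadata `exam_date`, `age`,
#' `exam_code`. CSV and JSONL (one JSON object per line) are supported; the
#' format is chosen by file extension (`.jsonl`/`.json` vs anything else).
#'
#' @param path file path.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return `read_corpus()` returns a data.frame; `write_corpus()` its input,
#'   invisibly.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  }
  if (!all(c("id", "text") %in% names(df))) {
    stop("corpus must have 'id' and 'text' columns")
  }
  df$id <- as.character(df$id)
  df$text <- as.character(df$text)
  if ("age" %in% names(df)) df$age <- suppressWarnings(as.numeric(df$age))
  if ("exam_date" %in% names(df)) df$exam_date <- as.Date(df$exam_date)
  df
}

#' @rdname read_corpus
#' @param corpus a corpus data.frame.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  out <- corpus
  if ("exam_date" %in% names(out)) out$exam_date <- as.character(out$exam_date)
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      writeLines(jsonlite::toJSON(as.list(out[i, , drop = FALSE]),
                                  auto_unbox = TRUE, na = "null"), con)
    }
  } else {
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(corpus)
}

#' Filter a corpus by inclusion/exclusion criteria
#'
#' Applies date-range, age, and exam-code filters, and optionally keeps only
#' the most recent report per pseudoidentifier (deduplication before
#' analysis, avoiding repeated patients). Reports missing metadata required
#' by an active criterion are excluded and reported via a message.
#'
#' @param reports corpus data.frame (see [read_corpus()]).
#' @param criteria a list with any of `date_from`, `date_to` (Dates or
#'   strings), `min_age`, `max_age` (years), `exam_codes` (character vector),
#'   `keep_most_recent` (logical).
#' @return The filtered data.frame, original column set preserved.
#' @export
filter_corpus <- function(reports, criteria = list()) {
  stopifnot(is.data.frame(reports))
  if (length(criteria) == 0L) return(reports)
  unknown <- setdiff(names(criteria),
                     c("date_from", "date_to", "min_age", "max_age",
                       "exam_codes", "keep_most_recent"))
  if (length(unknown)) stop("unknown filter criteria: ",
                            paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(reports))
  dropped_missing <- character(0)
  need <- function(col) {
    if (!col %in% names(reports)) rep(NA, nrow(reports)) else reports[[col]]
  }
  if (!is.null(criteria$date_from) || !is.null(criteria$date_to) ||
      isTRUE(criteria$keep_most_recent)) {
    dates <- as.Date(need("exam_date"))
    if (!is.null(criteria$date_from)) {
      ok <- !is.na(dates) & dates >= as.Date(criteria$date_from)
      dropped_missing <- c(dropped_missing, reports$id[is.na(dates) & keep])
      keep <- keep & ok
    }
    if (!is.null(criteria$date_to)) {
      ok <- !is.na(dates) & dates <= as.Date(criteria$date_to)
      dropped_missing <- c(dropped_missing, reports$id[is.na(dates) & keep])
      keep <- keep & ok
    }
  }
  if (!is.null(criteria$min_age) || !is.null(criteria$max_age)) {
    age <- suppressWarnings(as.numeric(need("age")))
    dropped_missing <- c(dropped_missing, reports$id[is.na(age) & keep])
    if (!is.null(criteria$min_age)) keep <- keep & !is.na(age) & age >= criteria$min_age
    if (!is.null(criteria$max_age)) keep <- keep & !is.na(age) & age <= criteria$max_age
  }
  if (!is.null(criteria$exam_codes)) {
    code <- as.character(need("exam_code"))
    dropped_missing <- c(dropped_missing, reports$id[is.na(code) & keep])
    keep <- keep & !is.na(code) & code %in% criteria$exam_codes
  }
  out <- reports[keep, , drop = FALSE]
  if (isTRUE(criteria$keep_most_recent) && nrow(out) > 0L) {
    dates <- as.Date(out$exam_date)
    miss <- is.na(dates)
    if (any(miss)) dropped_missing <- c(dropped_missing, out$id[miss])
    out <- out[!miss, , drop = FALSE]
    dates <- dates[!miss]
    # latest exam_date per id; stable for ties (last occurrence wins)
    ord <- order(out$id, dates, seq_len(nrow(out)))
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$id, fromLast = TRUE), , drop = FALSE]
    out <- out[order(match(out$id, reports$id)), , drop = FALSE]
  }
  dropped_missing <- unique(dropped_missing)
  if (length(dropped_missing)) {
    message(sprintf(
      "filter_corpus: %d report(s) excluded for missing metadata: %s",
      length(dropped_missing),
      paste(utils::head(dropped_missing, 5L), collapse = ", ")))
  }
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Sectioning
## ---------------------------------------------------------------------------

#' Split a report into sections at configured headers
#'
#' Headers are literal names matched case-insensitively at word boundaries
#' with an optional trailing colon. Text before the first header goes to the
#' `body` section; header text itself belongs to no section. A repeated
#' header contributes an additional segment to the same section.
#'
#' @param text raw report text (single string).
#' @param headers character vector of header names, e.g.
#'   `c("clinical history", "findings")`.
#' @return A data.frame of segments with columns `name`, `start`, `end`
#'   (1-based inclusive raw offsets of the segment text) and `text`. Segments
#'   appear in document order; a headerless report yields one `body` segment.
#' @export
split_sections <- function(text, headers = character(0)) {
  stopifnot(is.character(text), length(text) == 1L)
  nchar_text <- nchar(text)
  hits <- data.frame(name = character(0), start = integer(0),
                     hdr_end = integer(0), stringsAsFactors = FALSE)
  for (h in headers) {
    esc <- gsub("([.\\\\|()\\[\\]{}^$+*?])", "\\\\\\1", h, perl = TRUE)
    pat <- paste0("(?i)(?<![A-Za-z0-9])", gsub(" ", "\\\\s+", esc),
                  "\\s*:?")
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hits <- rbind(hits, data.frame(
      name = tolower(h), start = as.integer(m),
      hdr_end = as.integer(m) + attr(m, "match.length") - 1L,
      stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  segs <- list()
  add_seg <- function(name, start, end) {
    if (end < start) return()
    segs[[length(segs) + 1L]] <<- data.frame(
      name = name, start = start, end = end,
      text = substr(text, start, end), stringsAsFactors = FALSE)
  }
  if (nrow(hits) == 0L) {
    add_seg("body", 1L, nchar_text)
  } else {
    if (hits$start[1] > 1L) add_seg("body", 1L, hits$start[1] - 1L)
    for (i in seq_len(nrow(hits))) {
      seg_start <- hits$hdr_end[i] + 1L
      seg_end <- if (i < nrow(hits)) hits$start[i + 1L] - 1L else nchar_text
      add_seg(hits$name[i], seg_start, seg_end)
    }
  }
  out <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), text = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

## ---------------------------------------------------------------------------
## Standardisation with offset maps
## ---------------------------------------------------------------------------

# Small default stopword list; removal is OFF by default because proximity
# gaps count intervening words, and dropping stopwords changes those counts.
radex_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "been", "by", "for", "from",
    "has", "have", "in", "is", "it", "its", "of", "on", "or", "that", "the",
    "there", "this", "to", "was", "were", "which", "with")
}

# Unit tokens guarded against sentence splits ("3 mm. ..." is not an
# abbreviation but a mid-sentence measurement in terse clinical prose).
abbrev_guard_tokens <- function() {
  c("mm", "cm", "ml", "mg", "mhz", "khz", "approx", "vs", "dr")
}

#' Standardise section text into sentences with offset maps
#'
#' Lowercases, maps punctuation (including `/`, `-`, parentheses) to word
#' separators while preserving decimal points inside numbers, collapses
#' whitespace, and splits into sentences at `.`, `!`, `?` and blank lines.
#' Single-letter and unit tokens guard against false splits. Every character
#' of every output sentence is traceable to a raw-text position.
#'
#' @param text a single string (typically one section segment).
#' @param remove_stopwords drop stopword tokens (default `FALSE`; proximity
#'   gap counts then refer to the surviving tokens only).
#' @param stopwords stopword list used when removal is enabled.
#' @return A list of sentences, each a list with `text` (standardised
#'   sentence) and `offsets` (integer vector, one 1-based raw-text position
#'   per sentence character, strictly increasing).
#' @export
standardise <- function(text, remove_stopwords = FALSE,
                        stopwords = radex_stopwords()) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(list())
  low <- tolower(chars)
  is_word <- grepl("^[a-z0-9]$", low)
  is_final <- low %in% c(".", "!", "?")

  # decimal points inside numbers are kept as token characters
  is_digit <- grepl("^[0-9]$", low)
  keep_dot <- low == "." &
    c(FALSE, is_digit[-n]) & c(is_digit[-1], FALSE)
  kept <- is_word | keep_dot

  # sentence boundaries: final punctuation directly after a word character,
  # unless guarded; plus blank lines
  boundary <- rep(FALSE, n)
  prev_word <- c(FALSE, is_word[-n])
  prev_closer <- c(FALSE, low[-n] %in% c(")", "]", "\"", "'"))
  cand <- which(is_final & !keep_dot & (prev_word | prev_closer))
  if (length(cand)) {
    # token length run ending just before the candidate
    r <- rle(kept)
    run_end <- cumsum(r$lengths)
    run_start_at <- rep(run_end - r$lengths + 1L, r$lengths)
    for (p in cand) {
      if (low[p] %in% c("!", "?") || prev_closer[p]) {
        boundary[p] <- TRUE
        next
      }
      tok_start <- run_start_at[p - 1L]
      tok <- paste(low[tok_start:(p - 1L)], collapse = "")
      if (nchar(tok) == 1L && grepl("^[a-z]$", tok)) next  # initials etc.
      if (tok %in% abbrev_guard_tokens()) next
      boundary[p] <- TRUE
    }
  }
  nl <- low == "\n"
  if (n >= 2L) {
    dbl <- which(nl & c(nl[-1], FALSE))
    boundary[dbl] <- TRUE
  }

  sent_id <- cumsum(c(0L, boundary[-n])) + 1L
  out <- list()
  for (sid in unique(sent_id)) {
    pos <- which(sent_id == sid & !boundary)
    if (!length(pos)) next
    k <- kept[pos]
    if (!any(k)) next
    # trim non-kept runs at both ends, then emit kept runs joined by single
    # spaces anchored at the first raw position of each separator run
    first_k <- which(k)[1]
    last_k <- which(k)[length(which(k))]
    pos <- pos[first_k:last_k]
    k <- k[first_k:last_k]
    r <- rle(k)
    idx <- 1L
    sent_chars <- character(0)
    sent_off <- integer(0)
    for (j in seq_along(r$lengths)) {
      run_pos <- pos[idx:(idx + r$lengths[j] - 1L)]
      if (r$values[j]) {
        sent_chars <- c(sent_chars, low[run_pos])
        sent_off <- c(sent_off, run_pos)
      } else {
        sent_chars <- c(sent_chars, " ")
        sent_off <- c(sent_off, run_pos[1])
      }
      idx <- idx + r$lengths[j]
    }
    sentence <- list(text = paste(sent_chars, collapse = ""),
                     offsets = sent_off)
    if (remove_stopwords) {
      sentence <- drop_stopwords(sentence, stopwords)
      if (is.null(sentence)) next
    }
    out[[length(out) + 1L]] <- sentence
  }
  out
}

# Remove stopword tokens from a standardised sentence, keeping offsets
# consistent.
drop_stopwords <- function(sentence, stopwords) {
  chars <- strsplit(sentence$text, "", fixed = TRUE)[[1]]
  is_sep <- chars == " "
  tok_id <- cumsum(c(TRUE, diff(is_sep) != 0L))
  keep_char <- rep(TRUE, length(chars))
  for (tid in unique(tok_id[!is_sep])) {
    sel <- tok_id == tid
    tok <- paste(chars[sel], collapse = "")
    if (tok %in% stopwords) keep_char[sel] <- FALSE
  }
  chars <- chars[keep_char]
  offs <- sentence$offsets[keep_char]
  # collapse any resulting multi-space runs and trim
  if (!length(chars)) return(NULL)
  sp <- chars == " "
  dup <- sp & c(FALSE, sp[-length(sp)])
  chars <- chars[!dup]; offs <- offs[!dup]
  while (length(chars) && chars[1] == " ") { chars <- chars[-1]; offs <- offs[-1] }
  while (length(chars) && chars[length(chars)] == " ") {
    chars <- chars[-length(chars)]; offs <- offs[-length(offs)]
  }
  if (!length(chars)) return(NULL)
  list(text = paste(chars, collapse = ""), offsets = offs)
}

#' Preprocess a single report
#'
#' Runs sectioning and standardisation, producing the processed
#' representation consumed by [classify_report()].
#'
#' @param report a one-row corpus data.frame or a list with `id` and `text`.
#' @param headers section header names (see [split_sections()]).
#' @param remove_stopwords passed to [standardise()].
#' @return An object of class `radex_processed`: list with `id`, `raw`,
#'   `segments` (section segment table) and `sentences`, a list of
#'   `list(section, text, offsets)` with offsets absolute in the raw report.
#' @export
process_report <- function(report, headers = character(0),
                           remove_stopwords = FALSE) {
  id <- as.character(report$id)
  text <- as.character(report$text)
  segs <- split_sections(text, headers)
  sentences <- list()
  for (i in seq_len(nrow(segs))) {
    std <- standardise(segs$text[i], remove_stopwords = remove_stopwords)
    for (s in std) {
      sentences[[length(sentences) + 1L]] <- list(
        section = segs$name[i],
        text = s$text,
        offsets = s$offsets + segs$start[i] - 1L)
    }
  }
  structure(list(id = id, raw = text, segments = segs,
                 sentences = sentences),
            class = "radex_processed")
}

#' @export
print.radex_processed <- function(x, ...) {
  cat(sprintf("<processed report %s: %d section segment(s), %d sentence(s)>\n",
              x$id, nrow(x$segments), length(x$sentences)))
  invisible(x)
}
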