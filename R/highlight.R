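## ---------------------------------------------------------------------------
## Evidence highlighting: standalone HTML with one style per class over the
## raw report text, negation triggers marked distinctly. Stripping the markup
## reproduces the raw text exactly, because spans are defined on raw offsets.
## ---------------------------------------------------------------------------

highlight_palette <- function(n) {
  base <- c("#aecbfa", "#b7e1cd", "#d7aefb", "#e6c9a8", "#fad2cf",
            "#fff475", "#cbf0f8", "#fdcfe8", "#ccff90", "#ffd6a5",
            "#d3bfdb", "#a7ffeb", "#f6aea9", "#c9def8")
  rep(base, length.out = n)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

#' Highlight a classified report
#'
#' Renders the raw report as a standalone HTML document with one colour per
#' class over its (non-negated) evidence spans, overlapping spans of the same
#' class merged, and negation trigger phrases underlined. Span offsets come
#' straight from the classification evidence, so [strip_highlight()] on the
#' output reproduces the raw text exactly.
#'
#' @param result a `radex_result` (which carries the raw text).
#' @param classes classes to render; default all with evidence.
#' @param title document title.
#' @return A single character string of HTML.
#' @export
highlight_report <- function(result, classes = NULL, title = NULL) {
  raw <- result$raw
  n <- nchar(raw)
  classes <- classes %||% names(result$evidence)
  classes <- classes[vapply(classes, function(cl) {
    ev <- result$evidence[[cl]]
    !is.null(ev) && nrow(ev) > 0L
  }, logical(1))]
  pal <- highlight_palette(length(classes))

  # per-character annotation: class index bitmask as list of integer vectors
  ann <- vector("list", n)
  trig <- rep(FALSE, n)
  for (k in seq_along(classes)) {
    ev <- result$evidence[[classes[k]]]
    for (i in seq_len(nrow(ev))) {
      if (ev$start[i] < 1L || ev$end[i] > n) {
        stop("evidence span outside raw text for class '", classes[k], "'")
      }
      if (!ev$negated[i]) {
        for (p in ev$start[i]:ev$end[i]) ann[[p]] <- union(ann[[p]], k)
      }
      if (!is.na(ev$trigger_start[i])) {
        trig[ev$trigger_start[i]:ev$trigger_end[i]] <- TRUE
      }
    }
  }

  key <- vapply(seq_len(n), function(p) {
    paste(c(ann[[p]], if (trig[p]) "T"), collapse = ",")
  }, character(1))
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pieces <- character(length(runs$values))
  for (j in seq_along(runs$values)) {
    txt <- html_escape(substr(raw, starts[j], ends[j]))
    cls_ids <- ann[[starts[j]]]
    classes_attr <- character(0)
    if (length(cls_ids)) classes_attr <- paste0("c", cls_ids)
    if (trig[starts[j]]) classes_attr <- c(classes_attr, "neg")
    pieces[j] <- if (length(classes_attr)) {
      sprintf("<mark class=\"%s\">%s</mark>",
              paste(classes_attr, collapse = " "), txt)
    } else {
      txt
    }
  }

  css <- paste(vapply(seq_along(classes), function(k) {
    sprintf(".c%d { background-color: %s; }", k, pal[k])
  }, character(1)), collapse = "\n")
  legend <- paste(vapply(seq_along(classes), function(k) {
    sprintf("<span class=\"legend c%d\">%s</span>", k,
            html_escape(classes[k]))
  }, character(1)), collapse = " ")
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>\n",
    "<title>", html_escape(title %||% paste("report", result$id)),
    "</title>\n<style>\n",
    "body { font-family: sans-serif; max-width: 50em; margin: 2em auto; }\n",
    "pre.report { white-space: pre-wrap; font-size: 1em; }\n",
    "mark.neg { background-color: inherit; text-decoration: underline wavy; }\n",
    "mark.neg[class*=c] { text-decoration: underline wavy; }\n",
    ".legend { padding: 0 0.4em; margin-right: 0.4em; }\n",
    css, "\n</style></head><body>\n",
    "<h2>Report ", html_escape(result$id), "</h2>\n",
    "<p>", legend, "</p>\n",
    "<pre class=\"report\">", paste(pieces, collapse = ""), "</pre>\n",
    "</body></html>\n")
}

#' Strip highlight markup
#'
#' Inverse of [highlight_report()]: extracts the report text from a
#' highlighted HTML document, reproducing the raw text exactly.
#'
#' @param html character string produced by [highlight_report()].
#' @return The raw report text.
#' @export
strip_highlight <- function(html) {
  m <- regexpr("(?s)<pre class=\"report\">.*</pre>", html, perl = TRUE)
  stopifnot(m > 0L)
  body <- substr(html, m + nchar("<pre class=\"report\">"),
                 m + attr(m, "match.length") - 1L - nchar("</pre>"))
  body <- gsub("</?mark[^>]*>", "", body)
  body <- gsub("&lt;", "<", body, fixed = TRUE)
  body <- gsub("&gt;", ">", body, fixed = TRUE)
  body <- gsub("&amp;", "&", body, fixed = TRUE)
  body
}
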