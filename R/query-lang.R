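`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Query AST
##
## A search expression is parsed into a tree of nodes, each a list with a
## `type` field:
##   term     - atoms: character vector of word-atoms; '*' = zero-or-more word
##              characters, '?' = zero-or-one word character; multi-atom
##              vectors denote an exact adjacent phrase
##   classref - name: label of a previously defined class (derived classes)
##   near     - left, right (term nodes), gap: bidirectional proximity
##   then     - left, right (term nodes), gap: order-dependent proximity
##   and/or   - children: list of >= 2 nodes
##   not      - child
## ---------------------------------------------------------------------------

new_query <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "radex_query")
}

#' Query AST constructors
#'
#' Build query nodes programmatically. Most users write expressions in the
#' query language and call [parse_query()]; the constructors are exposed for
#' tests and tooling.
#'
#' @param atoms character vector of word-atoms (may contain `*` and `?`
#'   modifiers); multiple atoms denote an exact adjacent phrase.
#' @param name class label referenced by a derived-class expression.
#' @param left,right term nodes (proximity operands must be term patterns).
#' @param gap maximum number of intervening words (integer >= 0).
#' @param children list of at least two query nodes.
#' @param child a query node.
#' @return A `radex_query` node.
#' @export
query_term <- function(atoms) {
  atoms <- as.character(atoms)
  stopifnot(length(atoms) >= 1L, all(nzchar(atoms)))
  new_query("term", atoms = atoms)
}

#' @rdname query_term
#' @export
query_classref <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  new_query("classref", name = name)
}

#' @rdname query_term
#' @export
query_near <- function(left, right, gap) {
  stopifnot(identical(left$type, "term"), identical(right$type, "term"))
  gap <- as.integer(gap)
  stopifnot(length(gap) == 1L, !is.na(gap), gap >= 0L)
  new_query("near", left = left, right = right, gap = gap)
}

#' @rdname query_term
#' @export
query_then <- function(left, right, gap) {
  stopifnot(identical(left$type, "term"), identical(right$type, "term"))
  gap <- as.integer(gap)
  stopifnot(length(gap) == 1L, !is.na(gap), gap >= 0L)
  new_query("then", left = left, right = right, gap = gap)
}

#' @rdname query_term
#' @export
query_and <- function(children) {
  stopifnot(is.list(children), length(children) >= 2L)
  new_query("and", children = children)
}

#' @rdname query_term
#' @export
query_or <- function(children) {
  stopifnot(is.list(children), length(children) >= 2L)
  new_query("or", children = children)
}

#' @rdname query_term
#' @export
query_not <- function(child) {
  new_query("not", child = child)
}

## ---------------------------------------------------------------------------
## Parse errors: signalled as conditions of class "radex_parse_error" with a
## position (1-based character index), a kind, and optionally the strategy
## class the expression belongs to.
## ---------------------------------------------------------------------------

parse_error <- function(kind, position, message, class_name = NULL) {
  structure(
    class = c("radex_parse_error", "error", "condition"),
    list(message = message, call = NULL,
         kind = kind, position = position, class_name = class_name)
  )
}

stop_parse <- function(kind, position, message) {
  stop(parse_error(kind, position, message))
}

#' @export
print.radex_parse_error <- function(x, ...) {
  cat(sprintf("<parse error: %s at position %s> %s\n",
              x$kind, x$position %||% NA, x$message))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Tokeniser
## ---------------------------------------------------------------------------

token <- function(type, pos, value = NULL, gap = NULL) {
  list(type = type, pos = pos, value = value, gap = gap)
}

# Typographic variants that appear in printed strategies.
normalise_expression <- function(x) {
  x <- gsub("\u223c", "~", x)            # tilde operator
  x <- gsub("[\u201c\u201d\u2033]", "\"", x) # curly double quotes
  x
}

#' Tokenise a search expression
#'
#' Splits a query expression into a token stream. Both the verbose spellings
#' (`AND`, `OR`, `NOT`, `EXCEPT`, `NEAR/X`, `THEN/X`) and the shorthand
#' symbols (`&`, `|`, `\u00ac` (logical-not sign), `~X`) are accepted and map to the same tokens;
#' operator words are case-insensitive. Double quotes delimit references to
#' previously defined classes.
#'
#' @param expression a single character string.
#' @return A list of tokens, each a list with `type` (one of `TERM`,
#'   `CLASSREF`, `LPAREN`, `RPAREN`, `AND`, `OR`, `NOT`, `EXCEPT`, `NEAR`,
#'   `THEN`), `pos` (1-based character index) and, where relevant, `value`
#'   or `gap`.
#' @seealso [parse_query()]
#' @export
tokenize <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1L)
  if (!nzchar(trimws(expression))) {
    stop_parse("dangling_operator", 1L, "empty expression")
  }
  expression <- normalise_expression(expression)
  chars <- strsplit(expression, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", n)
  nt <- 0L
  push <- function(tk) {
    nt <<- nt + 1L
    toks[[nt]] <<- tk
  }
  is_word_char <- function(ch) grepl("^[A-Za-z0-9*?]$", ch)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(") {
      push(token("LPAREN", i)); i <- i + 1L
    } else if (ch == ")") {
      push(token("RPAREN", i)); i <- i + 1L
    } else if (ch == "&") {
      push(token("AND", i)); i <- i + 1L
    } else if (ch == "|") {
      push(token("OR", i)); i <- i + 1L
    } else if (ch == "\u00ac") {
      push(token("NOT", i)); i <- i + 1L
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") j <- j + 1L
      if (j > n) {
        stop_parse("unexpected_symbol", i, "unterminated class reference quote")
      }
      name <- trimws(paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                           collapse = ""))
      if (!nzchar(name)) {
        stop_parse("unexpected_symbol", i, "empty class reference")
      }
      push(token("CLASSREF", i, value = name))
      i <- j + 1L
    } else if (ch == "~") {
      start <- i
      j <- i + 1L
      while (j <= n && grepl("^\\s$", chars[j])) j <- j + 1L
      k <- j
      while (k <= n && grepl("^[0-9]$", chars[k])) k <- k + 1L
      if (k == j) {
        stop_parse("bad_gap", start,
                   "proximity '~' must be followed by a non-negative integer")
      }
      gap <- as.integer(paste(chars[j:(k - 1L)], collapse = ""))
      push(token("NEAR", start, gap = gap))
      i <- k
    } else if (is_word_char(ch)) {
      j <- i
      while (j <= n && is_word_char(chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      lw <- tolower(word)
      if (lw %in% c("and", "or", "not", "except")) {
        push(token(toupper(lw), i))
        i <- j
      } else if (lw %in% c("near", "then") && j <= n && chars[j] == "/") {
        k <- j + 1L
        m <- k
        while (m <= n && grepl("^[0-9]$", chars[m])) m <- m + 1L
        if (m == k) {
          stop_parse("bad_gap", i, sprintf(
            "'%s/' must be followed by a non-negative integer", toupper(lw)))
        }
        gap <- as.integer(paste(chars[k:(m - 1L)], collapse = ""))
        push(token(toupper(lw), i, gap = gap))
        i <- m
      } else {
        push(token("TERM", i, value = lw))
        i <- j
      }
    } else {
      stop_parse("unexpected_symbol", i,
                 sprintf("unexpected symbol '%s' at position %d", ch, i))
    }
  }
  toks[seq_len(nt)]
}

## ---------------------------------------------------------------------------
## Parser: recursive descent with precedence NOT > AND > OR. Proximity
## (NEAR/X, THEN/X) binds tighter than NOT and only joins term patterns.
## EXCEPT desugars to AND(left, NOT(right)) at parse time. Adjacent bare
## terms merge into a single phrase pattern.
## ---------------------------------------------------------------------------

#' Parse a search expression into a query AST
#'
#' @param x a character expression or a token list from [tokenize()].
#' @return A `radex_query` node. Parse failures are signalled as conditions
#'   of class `radex_parse_error` carrying `kind` (one of
#'   `unmatched_parenthesis`, `unexpected_symbol`, `dangling_operator`,
#'   `unknown_class_reference`, `bad_gap`) and `position`.
#' @examples
#' parse_query("thyroid NEAR/2 nodules OR multinodular")
#' parse_query("node? EXCEPT lymph node?")
#' @export
parse_query <- function(x) {
  toks <- if (is.character(x)) tokenize(x) else x
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L
  state$n <- length(toks)

  peek <- function() if (state$i <= state$n) state$toks[[state$i]] else NULL
  advance <- function() {
    tk <- state$toks[[state$i]]
    state$i <- state$i + 1L
    tk
  }
  end_pos <- function() {
    if (state$n > 0L) state$toks[[state$n]]$pos else 1L
  }

  parse_or <- function() {
    children <- list(parse_and())
    while (!is.null(tk <- peek()) && tk$type == "OR") {
      advance()
      children <- c(children, list(parse_and()))
    }
    if (length(children) == 1L) children[[1]] else query_or(children)
  }

  parse_and <- function() {
    children <- list(parse_not())
    repeat {
      tk <- peek()
      if (is.null(tk) || !(tk$type %in% c("AND", "EXCEPT"))) break
      advance()
      rhs <- parse_not()
      if (tk$type == "EXCEPT") rhs <- query_not(rhs)
      children <- c(children, list(rhs))
    }
    if (length(children) == 1L) children[[1]] else query_and(children)
  }

  parse_not <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$type == "NOT") {
      advance()
      nxt <- peek()
      if (is.null(nxt)) {
        stop_parse("dangling_operator", tk$pos, "NOT is missing its operand")
      }
      return(query_not(parse_not()))
    }
    parse_primary()
  }

  parse_phrase <- function() {
    tk <- peek()
    if (is.null(tk) || tk$type != "TERM") {
      pos <- if (is.null(tk)) end_pos() else tk$pos
      stop_parse("dangling_operator", pos,
                 "proximity operator requires a term operand")
    }
    atoms <- character(0)
    while (!is.null(tk <- peek()) && tk$type == "TERM") {
      advance()
      atoms <- c(atoms, tk$value)
    }
    query_term(atoms)
  }

  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk)) {
      stop_parse("dangling_operator", end_pos(), "expression ended unexpectedly")
    }
    if (tk$type == "LPAREN") {
      advance()
      inner <- parse_or()
      closing <- peek()
      if (is.null(closing) || closing$type != "RPAREN") {
        stop_parse("unmatched_parenthesis", tk$pos,
                   "unmatched opening parenthesis")
      }
      advance()
      return(inner)
    }
    if (tk$type == "CLASSREF") {
      advance()
      return(query_classref(tk$value))
    }
    if (tk$type == "TERM") {
      left <- parse_phrase()
      tk2 <- peek()
      if (!is.null(tk2) && tk2$type %in% c("NEAR", "THEN")) {
        advance()
        right <- parse_phrase()
        node <- if (tk2$type == "NEAR") {
          query_near(left, right, tk2$gap)
        } else {
          query_then(left, right, tk2$gap)
        }
        tk3 <- peek()
        if (!is.null(tk3) && tk3$type %in% c("NEAR", "THEN")) {
          stop_parse("dangling_operator", tk3$pos,
                     "chained proximity operators are not supported")
        }
        return(node)
      }
      return(left)
    }
    if (tk$type == "RPAREN") {
      stop_parse("unmatched_parenthesis", tk$pos,
                 "unmatched closing parenthesis")
    }
    if (tk$type %in% c("NEAR", "THEN")) {
      stop_parse("dangling_operator", tk$pos,
                 "proximity operator is missing its left operand")
    }
    stop_parse("dangling_operator", tk$pos,
               sprintf("operator %s is missing an operand", tk$type))
  }

  out <- parse_or()
  tk <- peek()
  if (!is.null(tk)) {
    if (tk$type %in% c("RPAREN", "LPAREN")) {
      stop_parse("unmatched_parenthesis", tk$pos,
                 "unmatched parenthesis")
    }
    stop_parse("unexpected_symbol", tk$pos,
               sprintf("unexpected trailing %s", tk$type))
  }
  out
}

## ---------------------------------------------------------------------------
## Pretty printing / deparsing
## ---------------------------------------------------------------------------

#' Deparse a query AST back to query-language text
#'
#' Produces a verbose-syntax expression that re-parses to a structurally
#' identical AST.
#'
#' @param node a `radex_query` node.
#' @return A character string.
#' @export
deparse_query <- function(node) {
  paren <- function(child) {
    if (child$type %in% c("and", "or")) {
      paste0("(", deparse_query(child), ")")
    } else {
      deparse_query(child)
    }
  }
  switch(node$type,
    term = paste(node$atoms, collapse = " "),
    classref = paste0("\"", node$name, "\""),
    near = sprintf("%s NEAR/%d %s", deparse_query(node$left), node$gap,
                   deparse_query(node$right)),
    then = sprintf("%s THEN/%d %s", deparse_query(node$left), node$gap,
                   deparse_query(node$right)),
    not = paste("NOT", paren(node$child)),
    and = paste(vapply(node$children, function(ch) {
      if (ch$type == "or") paste0("(", deparse_query(ch), ")") else paren(ch)
    }, character(1)), collapse = " AND "),
    or = paste(vapply(node$children, paren, character(1)), collapse = " OR "),
    stop("unknown node type: ", node$type)
  )
}

#' @export
print.radex_query <- function(x, ...) {
  cat("<radex query> ", deparse_query(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.radex_query <- function(x, ...) deparse_query(x)

# All classref names appearing in a query.
query_classrefs <- function(node) {
  switch(node$type,
    classref = node$name,
    term = character(0),
    near = character(0),
    then = character(0),
    not = query_classrefs(node$child),
    and = ,
    or = unlist(lapply(node$children, query_classrefs)),
    character(0)
  )
}
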