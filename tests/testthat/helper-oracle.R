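# Independent brute-force oracles used to validate the package's regex
# compilation, recursive evaluation, parsing precedence, and metrics.
# These deliberately avoid the package's code paths: token-level window
# enumeration with set semantics instead of compiled regular expressions,
# naive loops instead of vectorised counts.

oracle_tokens <- function(sentence) {
  toks <- strsplit(tolower(sentence), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Does one atom (with '*' = 0+ word chars, '?' = 0/1 word char) match a
# whole token? Recursive matcher, no regex involved.
oracle_atom_match <- function(atom, token) {
  a <- strsplit(atom, "", fixed = TRUE)[[1]]
  t <- strsplit(token, "", fixed = TRUE)[[1]]
  rec <- function(i, j) {
    if (i > length(a)) return(j > length(t))
    ch <- a[i]
    if (ch == "*") {
      for (k in j:(length(t) + 1L)) {
        if (rec(i + 1L, k)) return(TRUE)
      }
      return(FALSE)
    }
    if (ch == "?") {
      if (rec(i + 1L, j)) return(TRUE)
      if (j <= length(t)) return(rec(i + 1L, j + 1L))
      return(FALSE)
    }
    if (j <= length(t) && t[j] == tolower(ch)) return(rec(i + 1L, j + 1L))
    FALSE
  }
  rec(1L, 1L)
}

# Start positions (token index) where a phrase of atoms matches adjacently;
# value: data.frame(start, end) in token indices.
oracle_phrase_positions <- function(atoms, tokens) {
  k <- length(atoms)
  out <- list()
  if (length(tokens) >= k && k >= 1L) {
    for (s in seq_len(length(tokens) - k + 1L)) {
      if (all(mapply(oracle_atom_match, atoms, tokens[s:(s + k - 1L)]))) {
        out[[length(out) + 1L]] <- c(s, s + k - 1L)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# Presence of a query in a sentence by exhaustive window enumeration and
# set-theoretic boolean semantics.
oracle_presence <- function(node, sentence, resolver = NULL) {
  tokens <- oracle_tokens(sentence)
  rec <- function(node) {
    switch(node$type,
      term = nrow(oracle_phrase_positions(node$atoms, tokens)) > 0L,
      near = ,
      then = {
        lp <- oracle_phrase_positions(node$left$atoms, tokens)
        rp <- oracle_phrase_positions(node$right$atoms, tokens)
        ok <- FALSE
        for (i in seq_len(nrow(lp))) {
          for (j in seq_len(nrow(rp))) {
            fwd_gap <- rp$start[j] - lp$end[i] - 1L
            bwd_gap <- lp$start[i] - rp$end[j] - 1L
            if (fwd_gap >= 0L && fwd_gap <= node$gap) ok <- TRUE
            if (node$type == "near" && bwd_gap >= 0L && bwd_gap <= node$gap) {
              ok <- TRUE
            }
          }
        }
        ok
      },
      classref = isTRUE(resolver(node$name)),
      and = all(vapply(node$children, rec, logical(1))),
      or = any(vapply(node$children, rec, logical(1))),
      not = !rec(node$child),
      stop("oracle: unknown node ", node$type)
    )
  }
  rec(node)
}

# --- random generators -----------------------------------------------------

oracle_vocab <- c("a", "b", "ab", "ba", "abc", "ca", "cb", "bc")

random_atom <- function(vocab = oracle_vocab) {
  w <- sample(vocab, 1L)
  r <- stats::runif(1)
  if (r < 0.2) {
    paste0(w, "*")
  } else if (r < 0.35) {
    paste0(substr(w, 1, 1), "?", substr(w, 2, nchar(w)))
  } else {
    w
  }
}

random_term_node <- function(vocab = oracle_vocab) {
  n_atoms <- if (stats::runif(1) < 0.2) 2L else 1L
  query_term(vapply(seq_len(n_atoms), function(i) random_atom(vocab),
                    character(1)))
}

# Random query with at most n_ops boolean/proximity operators.
random_query <- function(n_ops, vocab = oracle_vocab) {
  if (n_ops <= 0L) return(random_term_node(vocab))
  kind <- sample(c("and", "or", "not", "near", "then"), 1L,
                 prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
  if (kind == "not") {
    query_not(random_query(n_ops - 1L, vocab))
  } else if (kind %in% c("near", "then")) {
    gap <- sample(0:3, 1L)
    l <- random_term_node(vocab)
    r <- random_term_node(vocab)
    if (kind == "near") query_near(l, r, gap) else query_then(l, r, gap)
  } else {
    budget <- n_ops - 1L
    left <- sample(0:budget, 1L)
    children <- list(random_query(left, vocab),
                     random_query(budget - left, vocab))
    if (kind == "and") query_and(children) else query_or(children)
  }
}

random_sentence <- function(vocab = oracle_vocab, max_len = 10L) {
  n <- sample(0:max_len, 1L)
  paste(sample(vocab, n, replace = TRUE), collapse = " ")
}

# --- independent precedence parser ----------------------------------------
# Splits the token stream at the lowest-precedence operator present at
# parenthesis depth zero (OR, then AND/EXCEPT, then a NOT prefix), the
# opposite strategy to the package's recursive-descent parser.

oracle_parse <- function(expression) {
  toks <- tokenize(expression)
  parse_range <- function(lo, hi) {
    stopifnot(lo <= hi)
    depth <- 0L
    # strip a fully enclosing parenthesis pair
    repeat {
      if (toks[[lo]]$type == "LPAREN" && toks[[hi]]$type == "RPAREN") {
        d <- 0L
        wraps <- TRUE
        for (k in lo:hi) {
          if (toks[[k]]$type == "LPAREN") d <- d + 1L
          if (toks[[k]]$type == "RPAREN") d <- d - 1L
          if (d == 0L && k < hi) { wraps <- FALSE; break }
        }
        if (wraps) { lo <- lo + 1L; hi <- hi - 1L; next }
      }
      break
    }
    split_at <- function(types) {
      d <- 0L
      pos <- integer(0)
      for (k in lo:hi) {
        tt <- toks[[k]]$type
        if (tt == "LPAREN") d <- d + 1L
        else if (tt == "RPAREN") d <- d - 1L
        else if (d == 0L && tt %in% types) pos <- c(pos, k)
      }
      pos
    }
    or_pos <- split_at("OR")
    if (length(or_pos)) {
      bounds <- c(lo - 1L, or_pos, hi + 1L)
      return(query_or(lapply(seq_len(length(bounds) - 1L), function(i) {
        parse_range(bounds[i] + 1L, bounds[i + 1L] - 1L)
      })))
    }
    and_pos <- split_at(c("AND", "EXCEPT"))
    if (length(and_pos)) {
      bounds <- c(lo - 1L, and_pos, hi + 1L)
      kids <- lapply(seq_len(length(bounds) - 1L), function(i) {
        child <- parse_range(bounds[i] + 1L, bounds[i + 1L] - 1L)
        if (i > 1L && toks[[bounds[i]]]$type == "EXCEPT") {
          child <- query_not(child)
        }
        child
      })
      return(query_and(kids))
    }
    if (toks[[lo]]$type == "NOT") {
      return(query_not(parse_range(lo + 1L, hi)))
    }
    # remaining: terms and proximity
    if (toks[[lo]]$type == "TERM") {
      atoms <- character(0)
      k <- lo
      while (k <= hi && toks[[k]]$type == "TERM") {
        atoms <- c(atoms, toks[[k]]$value)
        k <- k + 1L
      }
      left <- query_term(atoms)
      if (k > hi) return(left)
      stopifnot(toks[[k]]$type %in% c("NEAR", "THEN"))
      right_atoms <- vapply((k + 1L):hi, function(m) toks[[m]]$value,
                            character(1))
      right <- query_term(right_atoms)
      return(if (toks[[k]]$type == "NEAR") {
        query_near(left, right, toks[[k]]$gap)
      } else {
        query_then(left, right, toks[[k]]$gap)
      })
    }
    if (toks[[lo]]$type == "CLASSREF") {
      stopifnot(lo == hi)
      return(query_classref(toks[[lo]]$value))
    }
    stop("oracle parser: unexpected token ", toks[[lo]]$type)
  }
  parse_range(1L, length(toks))
}

# Random boolean expression text over single-letter atoms.
random_bool_expression <- function(max_atoms = 6L) {
  atoms_left <- sample(2:max_atoms, 1L)
  rec <- function(budget, depth) {
    if (budget <= 1L || depth > 3L) return(sample(letters[1:6], 1L))
    split <- sample(seq_len(budget - 1L), 1L)
    op <- sample(c("AND", "OR", "EXCEPT"), 1L)
    lhs <- rec(split, depth + 1L)
    rhs <- rec(budget - split, depth + 1L)
    if (stats::runif(1) < 0.3) lhs <- paste0("(", lhs, ")")
    if (stats::runif(1) < 0.3) rhs <- paste0("(", rhs, ")")
    if (stats::runif(1) < 0.25) rhs <- paste("NOT", rhs)
    paste(lhs, op, rhs)
  }
  rec(atoms_left, 1L)
}

# --- naive reference implementation of the multi-label metrics -------------

oracle_multilabel <- function(pred, ref) {
  n <- nrow(pred)
  k <- ncol(pred)
  per <- list()
  tp_all <- fp_all <- fn_all <- tn_all <- 0
  for (j in seq_len(k)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(n)) {
      if (pred[i, j] && ref[i, j]) tp <- tp + 1
      if (pred[i, j] && !ref[i, j]) fp <- fp + 1
      if (!pred[i, j] && ref[i, j]) fn <- fn + 1
      if (!pred[i, j] && !ref[i, j]) tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    per[[j]] <- c(TP = tp, FP = fp, FN = fn, TN = tn, precision = prec,
                  sensitivity = sens, specificity = spec, f1 = f1)
    tp_all <- tp_all + tp; fp_all <- fp_all + fp
    fn_all <- fn_all + fn; tn_all <- tn_all + tn
  }
  wrong <- 0
  exact <- 0
  card <- 0
  for (i in seq_len(n)) {
    row_wrong <- 0
    for (j in seq_len(k)) {
      if (pred[i, j] != ref[i, j]) row_wrong <- row_wrong + 1
      if (ref[i, j]) card <- card + 1
    }
    wrong <- wrong + row_wrong
    if (row_wrong == 0) exact <- exact + 1
  }
  micro_prec <- if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else NA_real_
  micro_sens <- if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else NA_real_
  micro_spec <- if (tn_all + fp_all > 0) tn_all / (tn_all + fp_all) else NA_real_
  micro_f1 <- if (!is.na(micro_prec) && !is.na(micro_sens) &&
                  micro_prec + micro_sens > 0) {
    2 * micro_prec * micro_sens / (micro_prec + micro_sens)
  } else NA_real_
  list(per_class = per,
       micro = c(precision = micro_prec, sensitivity = micro_sens,
                 specificity = micro_spec, f1 = micro_f1),
       hamming = wrong / (n * k),
       emr = exact / n,
       cardinality = card / n,
       density = card / (n * k))
}

oracle_kappa <- function(a, b) {
  n <- length(a)
  agree <- sum(a == b) / n
  pe <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  if (pe >= 1) return(NA_real_)
  (agree - pe) / (1 - pe)
}

# --- small shared fixtures -------------------------------------------------

labels_df_from_matrix <- function(m, classes = NULL) {
  classes <- classes %||% paste0("C", seq_len(ncol(m)))
  df <- as.data.frame(m)
  names(df) <- classes
  cbind(data.frame(id = sprintf("R%03d", seq_len(nrow(m))),
                   stringsAsFactors = FALSE), df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
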