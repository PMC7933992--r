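lit_string <- function(gene, direction) paste0(gene, "^", direction)

# minimal-DNF canonical string for a monotone truth table over m literals;
# rows are indexed by bitmask (bit j-1 set = literal j passes)
gate_canonical_string <- function(table, literals) {
  m <- nrow(literals)
  rows <- which(table) - 1L
  minimal <- rows[vapply(rows, function(r) {
    subs <- rows[rows != r]
    !any(bitwAnd(subs, r) == subs)
  }, TRUE)]
  clauses <- lapply(sort(minimal), function(r) {
    js <- which(bitwAnd(r, bitwShiftL(1L, seq_len(m) - 1L)) > 0)
    lit_string(literals$gene[js], literals$direction[js])
  })
  strs <- vapply(clauses, paste, "", collapse = " & ")
  o <- order(lengths(clauses), strs)
  strs <- strs[o]
  if (length(strs) == 1) return(strs)
  wrapped <- ifelse(lengths(clauses)[o] > 1, paste0("(", strs, ")"), strs)
  paste(wrapped, collapse = " | ")
}

new_gate <- function(table, literals) {
  if (all(table) || !any(table)) stop_input("gate truth table is constant")
  string <- gate_canonical_string(table, literals)
  n_lit <- length(unique(unlist(regmatches(
    string, gregexpr("[A-Za-z][A-Za-z0-9_.-]*\\^(low|high)", string)))))
  structure(list(literals = literals, table = table, string = string,
                 n_literals = n_lit),
            class = "tm_gate")
}

#' @export
print.tm_gate <- function(x, ...) {
  cat("<tm_gate>", x$string, "\n")
  invisible(x)
}

#' @export
format.tm_gate <- function(x, ...) x$string

tokenize_gate <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { pos <- pos + nchar(ws); next }
    ch <- substr(text, pos, pos)
    if (ch %in% c("&", "|", "(", ")")) {
      tokens[[length(tokens) + 1]] <- list(type = ch, pos = pos)
      pos <- pos + 1L
      next
    }
    m <- regmatches(rest, regexpr("^([A-Za-z][A-Za-z0-9_.-]*)\\^([A-Za-z]+)", rest))
    if (!length(m)) {
      bare <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_.-]*", rest))
      if (length(bare)) {
        stop_input("literal '", bare, "' at position ", pos,
                   " lacks a ^low/^high direction suffix")
      }
      stop_input("gate syntax error at position ", pos, ": '", substr(rest, 1, 10), "'")
    }
    parts <- strsplit(sub("\\^", "\1", m), "\1")[[1]]
    if (!parts[2] %in% c("low", "high")) {
      stop_input("unknown direction suffix '^", parts[2], "' at position ", pos)
    }
    tokens[[length(tokens) + 1]] <- list(type = "lit", gene = parts[1],
                                         direction = parts[2], pos = pos)
    pos <- pos + nchar(m)
  }
  tokens
}

#' Parse a gate expression
#'
#' Mini-language mirroring the figure notation: literals are `GENE^low` or
#' `GENE^high`, combined with `&` (AND, binds tighter) and `|` (OR), with
#' parentheses. Example: `"CCR7^low & (FLT3LG^low | LTB^low)"`.
#'
#' @param text gate string.
#' @return A `tm_gate`: literal set, canonical truth table and canonical
#'   string (minimal disjunctive normal form).
#' @export
parse_gate <- function(text) {
  tokens <- tokenize_gate(text)
  if (!length(tokens)) stop_input("empty gate expression")
  i <- 0L
  peek <- function() if (i < length(tokens)) tokens[[i + 1L]] else NULL
  advance <- function() { i <<- i + 1L; tokens[[i]] }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      node <- list(type = "op", op = "|", a = node, b = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      node <- list(type = "op", op = "&", a = node, b = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) stop_input("gate syntax error: unexpected end of expression")
    if (tok$type == "lit") { advance(); return(tok) }
    if (tok$type == "(") {
      advance()
      node <- parse_expr()
      cl <- peek()
      if (is.null(cl) || cl$type != ")") stop_input("gate syntax error: missing ')'")
      advance()
      return(node)
    }
    stop_input("gate syntax error at position ", tok$pos, ": unexpected '", tok$type, "'")
  }
  tree <- parse_expr()
  if (i < length(tokens)) {
    stop_input("gate syntax error at position ", tokens[[i + 1]]$pos,
               ": unexpected '", tokens[[i + 1]]$type, "'")
  }
  lits <- list()
  collect <- function(node) {
    if (node$type == "lit") {
      key <- lit_string(node$gene, node$direction)
      lits[[key]] <<- list(gene = node$gene, direction = node$direction)
    } else {
      collect(node$a); collect(node$b)
    }
  }
  collect(tree)
  literals <- tibble::tibble(
    gene = vapply(lits, `[[`, "", "gene"),
    direction = vapply(lits, `[[`, "", "direction")
  )
  if (anyDuplicated(literals$gene)) {
    stop_input("gene used with conflicting directions: ",
               paste(literals$gene[duplicated(literals$gene)], collapse = ", "))
  }
  m <- nrow(literals)
  eval_tree <- function(node, states) {
    if (node$type == "lit") {
      return(states[match(lit_string(node$gene, node$direction),
                          lit_string(literals$gene, literals$direction))])
    }
    if (node$op == "&") eval_tree(node$a, states) & eval_tree(node$b, states)
    else eval_tree(node$a, states) | eval_tree(node$b, states)
  }
  table <- vapply(seq_len(2^m) - 1L, function(r) {
    eval_tree(tree, bitwAnd(r, bitwShiftL(1L, seq_len(m) - 1L)) > 0)
  }, TRUE)
  new_gate(table, literals)
}

#' Enumerate all monotone AND/OR gates over up to four literals
#'
#' All AND/OR expressions over every nonempty subset of the literals,
#' deduplicated by truth table (two expressions computing the same monotone
#' boolean function are the same gate). The counts for 1-4 literals are
#' 1, 4, 18 and 166 (the nonconstant monotone boolean functions).
#'
#' @param literals character vector of literal strings (`"GENE^low"` /
#'   `"GENE^high"`), or a tibble with `gene` and `direction` columns.
#' @param max_literals safety cap (default 4).
#' @return Named list of `tm_gate` objects keyed by canonical string.
#' @export
enumerate_gates <- function(literals, max_literals = 4) {
  if (is.character(literals)) {
    parts <- strsplit(literals, "^", fixed = TRUE)
    literals <- tibble::tibble(gene = vapply(parts, `[[`, "", 1),
                               direction = vapply(parts, `[[`, "", 2))
  }
  if (!all(literals$direction %in% c("low", "high"))) {
    stop_input("literal directions must be 'low' or 'high'")
  }
  m <- nrow(literals)
  if (m < 1 || m > max_literals) {
    stop_input("need between 1 and ", max_literals, " literals")
  }
  nrows <- 2^m
  idx <- seq_len(nrows) - 1L
  # each function is an integer bitmask over the 2^m truth-table rows
  lit_masks <- vapply(seq_len(m), function(j) {
    sum(bitwShiftL(1L, idx[bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0]))
  }, 1L)
  funcs <- unique(lit_masks)
  repeat {
    prs <- expand.grid(a = funcs, b = funcs)
    new_funcs <- unique(c(funcs, bitwAnd(prs$a, prs$b), bitwOr(prs$a, prs$b)))
    if (length(new_funcs) == length(funcs)) break
    funcs <- new_funcs
  }
  gates <- lapply(sort(funcs), function(f) {
    new_gate(bitwAnd(f, bitwShiftL(1L, idx)) > 0, literals)
  })
  names(gates) <- vapply(gates, `[[`, "", "string")
  gates[order(names(gates))]
}

gate_literal_states <- function(data, literals, threshold, thresholds = NULL) {
  states <- vapply(seq_len(nrow(literals)), function(j) {
    g <- literals$gene[j]
    if (!g %in% names(data)) stop_input("marker column not found: ", g)
    thr <- if (!is.null(thresholds) && g %in% names(thresholds)) thresholds[[g]] else threshold
    if (literals$direction[j] == "low") data[[g]] < thr else data[[g]] > thr
  }, logical(nrow(data)))
  if (nrow(data) == 1) states <- matrix(states, nrow = 1)
  states
}

#' Evaluate a gate's sensitivity, specificity and penalty
#'
#' A `^low` literal passes when expression is strictly below its threshold, a
#' `^high` literal when strictly above. The default universal threshold of
#' 0.001 UMI makes `^low` equivalent to "zero counts" on raw count data.
#' Penalty = Euclidean distance from perfect (sensitivity, specificity) plus
#' the absolute sensitivity-specificity difference, rewarding balanced gates.
#'
#' @param data data frame with one row per cell: marker columns (raw counts by
#'   default) plus a logical TM column.
#' @param gate a `tm_gate` (from [parse_gate()] / [enumerate_gates()]) or a
#'   gate string.
#' @param label_col name of the logical TM column (default `"is_tm"`).
#' @param threshold universal expression threshold (default 0.001 UMI).
#' @param thresholds optional named per-marker thresholds overriding the
#'   universal one (e.g. marker-test `cutoff_val`s).
#' @return One-row tibble: `gate`, `n_literals`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `penalty`.
#' @export
evaluate_gate <- function(data, gate, label_col = "is_tm", threshold = 0.001,
                          thresholds = NULL) {
  if (is.character(gate)) gate <- parse_gate(gate)
  if (!label_col %in% names(data)) stop_input("label column not found: ", label_col)
  truth <- as.logical(data[[label_col]])
  if (!any(truth) || all(truth)) stop_input("both TM and non-TM cells are required")
  states <- gate_literal_states(data, gate$literals, threshold, thresholds)
  row_idx <- as.integer(states %*% bitwShiftL(1L, seq_len(ncol(states)) - 1L)) + 1L
  pred <- gate$table[row_idx]
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  tibble::new_tibble(
    list(gate = gate$string, n_literals = gate$n_literals,
         tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         penalty = gate_penalty(sens, spec)),
    nrow = 1L
  )
}

#' @rdname evaluate_gate
#' @param sensitivity,specificity performance of a gate on pooled cells.
#' @export
gate_penalty <- function(sensitivity, specificity) {
  sqrt((1 - sensitivity)^2 + (1 - specificity)^2) + abs(sensitivity - specificity)
}

#' Evaluate a set of gates and flag the pareto frontier
#'
#' @param data as in [evaluate_gate()].
#' @param gates list of `tm_gate` objects (e.g. from [enumerate_gates()]) or
#'   character vector of gate strings.
#' @inheritParams evaluate_gate
#' @return A tibble with one row per gate (columns of [evaluate_gate()]) plus
#'   a logical `pareto` flag, sorted by penalty.
#' @export
evaluate_gates <- function(data, gates, label_col = "is_tm", threshold = 0.001,
                           thresholds = NULL) {
  if (is.character(gates)) gates <- lapply(gates, parse_gate)
  shared_literals <- length(gates) > 1 &&
    all(vapply(gates, function(g) identical(g$literals, gates[[1]]$literals), TRUE))
  if (shared_literals) {
    # one pass over the cells serves every gate on the common literal set
    if (!label_col %in% names(data)) stop_input("label column not found: ", label_col)
    truth <- as.logical(data[[label_col]])
    if (!any(truth) || all(truth)) stop_input("both TM and non-TM cells are required")
    states <- gate_literal_states(data, gates[[1]]$literals, threshold, thresholds)
    row_idx <- as.integer(states %*% bitwShiftL(1L, seq_len(ncol(states)) - 1L)) + 1L
    n_tm <- sum(truth); n_non <- sum(!truth)
    tm_rows <- tabulate(row_idx[truth], nbins = length(gates[[1]]$table))
    non_rows <- tabulate(row_idx[!truth], nbins = length(gates[[1]]$table))
    out <- purrr::map(gates, function(g) {
      tp <- sum(tm_rows[g$table]); fp <- sum(non_rows[g$table])
      sens <- tp / n_tm; spec <- (n_non - fp) / n_non
      tibble::new_tibble(
        list(gate = g$string, n_literals = g$n_literals,
             tp = tp, fp = fp, tn = n_non - fp, fn = n_tm - tp,
             sensitivity = sens, specificity = spec,
             penalty = gate_penalty(sens, spec)),
        nrow = 1L)
    }) |> dplyr::bind_rows()
  } else {
    out <- purrr::map(gates, evaluate_gate, data = data, label_col = label_col,
                      threshold = threshold, thresholds = thresholds) |>
      dplyr::bind_rows()
  }
  out$pareto <- pareto_filter(out)
  structure(dplyr::arrange(out, .data$penalty, .data$n_literals, .data$gate),
            class = c("tm_gate_evals", class(out)))
}

#' Pareto-optimality flags for gate evaluations
#'
#' A gate is pareto-optimal when no other gate is at least as good on both
#' sensitivity and specificity and strictly better on at least one.
#'
#' @param evals data frame with `sensitivity` and `specificity` columns.
#' @return Logical vector aligned with the rows of `evals`.
#' @export
pareto_filter <- function(evals) {
  if (nrow(evals) == 0) stop_input("no gate evaluations supplied")
  sens <- evals$sensitivity
  spec <- evals$specificity
  o <- order(-sens, -spec)
  flag <- logical(length(sens))
  best_spec_strictly_higher <- -Inf  # max spec among points with strictly higher sens
  i <- 1L
  while (i <= length(o)) {
    # group of points tied on sensitivity
    j <- i
    while (j < length(o) && sens[o[j + 1]] == sens[o[i]]) j <- j + 1L
    grp <- o[i:j]
    max_spec_grp <- max(spec[grp])
    flag[grp] <- spec[grp] >= max_spec_grp & spec[grp] > best_spec_strictly_higher
    best_spec_strictly_higher <- max(best_spec_strictly_higher, max_spec_grp)
    i <- j + 1L
  }
  flag
}

#' Select the penalty-minimizing gate
#'
#' By default the candidate set is first restricted to the pareto frontier:
#' the balance term of the penalty can otherwise prefer a gate that another
#' gate beats on both axes, which is never the right pick. Ties are broken by
#' fewer literals, then by lexicographic canonical string.
#'
#' @param evals tibble from [evaluate_gates()].
#' @param pareto_only restrict the choice to non-dominated gates (default
#'   `TRUE`).
#' @return The selected one-row evaluation.
#' @export
select_best_gate <- function(evals, pareto_only = TRUE) {
  if (nrow(evals) == 0) stop_input("no gate evaluations supplied")
  evals <- tibble::as_tibble(evals)
  if (pareto_only) evals <- evals[pareto_filter(evals), ]
  dplyr::arrange(evals, .data$penalty, .data$n_literals, .data$gate)[1, ]
}
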