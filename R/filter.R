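# Include-expression engine: tokenizer, recursive-descent parser, static
# type check against the known field aliases, and a per-record evaluator.
#
# Precedence (high to low): unary ! and -, then * /, then + -, then
# comparisons < <= > >= == !=, then &&, then ||; all left-associative;
# parentheses group. String-typed identifiers support only == and != against
# quoted string literals. The root expression must be boolean-typed.

TOKEN_PATTERNS <- list(
  c("num", "^(?:[0-9]+\\.[0-9]*|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?"),
  c("ident", "^[A-Za-z_][A-Za-z0-9_]*"),
  c("str", "^(?:'[^']*'|\"[^\"]*\")"),
  c("op", "^(?:\\|\\||&&|==|!=|<=|>=|[-+*/!<>()])")
)

#' @noRd
tokenize_expr <- function(text) {
  tokens <- list()
  pos <- 1L
  rest <- text
  while (nzchar(rest)) {
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(ws) == 1) {
      pos <- pos + nchar(ws)
      rest <- substring(rest, nchar(ws) + 1L)
      if (!nzchar(rest)) break
    }
    matched <- FALSE
    for (tp in TOKEN_PATTERNS) {
      m <- regmatches(rest, regexpr(tp[2], rest))
      if (length(m) == 1) {
        tokens[[length(tokens) + 1L]] <- list(type = tp[1], text = m, pos = pos)
        pos <- pos + nchar(m)
        rest <- substring(rest, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("syntax error at position %d: unexpected '%s'",
                   pos, substr(rest, 1, 1)), call. = FALSE)
    }
  }
  tokens
}

# parser state: environment with tokens and cursor
new_parser <- function(tokens, text) {
  p <- new.env(parent = emptyenv())
  p$tokens <- tokens
  p$i <- 1L
  p$text <- text
  p
}

peek <- function(p) if (p$i <= length(p$tokens)) p$tokens[[p$i]] else NULL

advance <- function(p) {
  t <- peek(p)
  p$i <- p$i + 1L
  t
}

expect_op <- function(p, op) {
  t <- peek(p)
  if (is.null(t) || t$type != "op" || t$text != op) {
    at <- if (is.null(t)) nchar(p$text) + 1L else t$pos
    stop(sprintf("syntax error at position %d: expected '%s'", at, op), call. = FALSE)
  }
  advance(p)
}

at_op <- function(p, ops) {
  t <- peek(p)
  !is.null(t) && t$type == "op" && t$text %in% ops
}

parse_primary <- function(p) {
  t <- peek(p)
  if (is.null(t)) {
    stop(sprintf("syntax error at position %d: unexpected end of expression",
                 nchar(p$text) + 1L), call. = FALSE)
  }
  if (t$type == "num") {
    advance(p)
    return(list(kind = "num", value = as.numeric(t$text), pos = t$pos))
  }
  if (t$type == "str") {
    advance(p)
    return(list(kind = "str", value = substr(t$text, 2, nchar(t$text) - 1L), pos = t$pos))
  }
  if (t$type == "ident") {
    advance(p)
    return(list(kind = "ident", name = t$text, pos = t$pos))
  }
  if (t$type == "op" && t$text == "(") {
    advance(p)
    e <- parse_or(p)
    expect_op(p, ")")
    return(e)
  }
  stop(sprintf("syntax error at position %d: unexpected '%s'", t$pos, t$text), call. = FALSE)
}

parse_unary <- function(p) {
  if (at_op(p, c("!", "-"))) {
    t <- advance(p)
    return(list(kind = "unary", op = t$text, operand = parse_unary(p), pos = t$pos))
  }
  parse_primary(p)
}

parse_binary_level <- function(p, ops, sub) {
  lhs <- sub(p)
  while (at_op(p, ops)) {
    t <- advance(p)
    lhs <- list(kind = "binary", op = t$text, lhs = lhs, rhs = sub(p), pos = t$pos)
  }
  lhs
}

parse_mul <- function(p) parse_binary_level(p, c("*", "/"), parse_unary)
parse_add <- function(p) parse_binary_level(p, c("+", "-"), parse_mul)
parse_cmp <- function(p) parse_binary_level(p, c("<", "<=", ">", ">=", "==", "!="), parse_add)
parse_and <- function(p) parse_binary_level(p, "&&", parse_cmp)
parse_or <- function(p) parse_binary_level(p, "||", parse_and)

# static type check: returns "num", "str" or "bool"; signals expression
# errors for unknown identifiers and type mismatches
typecheck_expr <- function(ast, types) {
  tc <- function(node) {
    switch(node$kind,
      num = "num",
      str = "str",
      ident = {
        if (!(node$name %in% names(types))) {
          stop(sprintf("expression error: unknown field '%s' at position %d",
                       node$name, node$pos), call. = FALSE)
        }
        types[[node$name]]
      },
      unary = {
        t <- tc(node$operand)
        want <- if (node$op == "!") "bool" else "num"
        if (t != want) {
          stop(sprintf("expression error: unary '%s' needs a %s operand at position %d",
                       node$op, if (want == "bool") "boolean" else "numeric", node$pos),
               call. = FALSE)
        }
        want
      },
      binary = {
        lt <- tc(node$lhs)
        rt <- tc(node$rhs)
        if (node$op %in% c("&&", "||")) {
          if (lt != "bool" || rt != "bool") {
            stop(sprintf("expression error: '%s' needs boolean operands at position %d",
                         node$op, node$pos), call. = FALSE)
          }
          "bool"
        } else if (node$op %in% c("==", "!=")) {
          if (!(lt == rt && lt %in% c("num", "str"))) {
            stop(sprintf("expression error: '%s' compares mismatched types at position %d",
                         node$op, node$pos), call. = FALSE)
          }
          "bool"
        } else if (node$op %in% c("<", "<=", ">", ">=")) {
          if (lt != "num" || rt != "num") {
            stop(sprintf("expression error: '%s' needs numeric operands at position %d",
                         node$op, node$pos), call. = FALSE)
          }
          "bool"
        } else {  # + - * /
          if (lt != "num" || rt != "num") {
            stop(sprintf("expression error: arithmetic '%s' needs numeric operands at position %d",
                         node$op, node$pos), call. = FALSE)
          }
          "num"
        }
      })
  }
  tc(ast)
}

#' Parse an include expression
#'
#' @param text Expression text, e.g. `"gnomad_popmax_af < 0.01"`.
#' @param types Named character vector mapping each known field alias to
#'   `"num"` or `"str"`. When supplied, identifiers and operand types are
#'   checked once, before any record is evaluated.
#' @return A `varchive_filter` object.
#' @export
#' @examples
#' parse_filter("nhomalt / (an / 2) < 0.005", c(nhomalt = "num", an = "num"))
parse_filter <- function(text, types = NULL) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stop("syntax error: empty filter expression", call. = FALSE)
  }
  p <- new_parser(tokenize_expr(text), text)
  ast <- parse_or(p)
  t <- peek(p)
  if (!is.null(t)) {
    stop(sprintf("syntax error at position %d: unexpected '%s'", t$pos, t$text), call. = FALSE)
  }
  if (!is.null(types)) {
    root_type <- typecheck_expr(ast, types)
    if (root_type != "bool") {
      stop("expression error: filter must be boolean-typed at its root", call. = FALSE)
    }
  }
  structure(list(ast = ast, text = text,
                 idents = unique(collect_idents(ast))), class = "varchive_filter")
}

#' @noRd
collect_idents <- function(node) {
  switch(node$kind,
         ident = node$name,
         unary = collect_idents(node$operand),
         binary = c(collect_idents(node$lhs), collect_idents(node$rhs)),
         character(0))
}

div_zero_condition <- function(pos) {
  structure(class = c("varchive_div_zero", "condition"),
            list(message = sprintf("division by zero at position %d", pos), call = NULL))
}

#' Evaluate a parsed filter for one record
#'
#' `&&` and `||` short-circuit; division is real-valued. Division by zero
#' signals a `varchive_div_zero` condition, which [filter_passes()] turns
#' into "record does not pass".
#'
#' @param filter A `varchive_filter` from [parse_filter()].
#' @param env Named list mapping every identifier in the expression to a
#'   numeric or string value.
#' @return `TRUE` or `FALSE`.
#' @export
eval_filter <- function(filter, env) {
  ev <- function(node) {
    switch(node$kind,
      num = node$value,
      str = node$value,
      ident = {
        v <- env[[node$name]]
        if (is.null(v)) {
          stop(sprintf("expression error: no value for '%s'", node$name), call. = FALSE)
        }
        v
      },
      unary = if (node$op == "!") !ev(node$operand) else -ev(node$operand),
      binary = {
        if (node$op == "&&") {
          return(if (!ev(node$lhs)) FALSE else ev(node$rhs))
        }
        if (node$op == "||") {
          return(if (ev(node$lhs)) TRUE else ev(node$rhs))
        }
        l <- ev(node$lhs)
        r <- ev(node$rhs)
        switch(node$op,
               "+" = l + r, "-" = l - r, "*" = l * r,
               "/" = {
                 if (r == 0) stop(div_zero_condition(node$pos))
                 l / r
               },
               "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r,
               "==" = l == r, "!=" = l != r)
      })
  }
  out <- ev(filter$ast)
  if (!is.logical(out)) {
    stop("expression error: filter did not evaluate to a boolean", call. = FALSE)
  }
  out
}

#' @rdname eval_filter
#' @details `filter_passes()` evaluates the filter and maps a division by
#'   zero to `FALSE` (the record does not pass), warning once per session of
#'   first occurrence via `warn_once`.
#' @param warn_once Environment used to emit the division-by-zero warning a
#'   single time; pass the same environment across records.
#' @export
filter_passes <- function(filter, env, warn_once = NULL) {
  tryCatch(eval_filter(filter, env),
           varchive_div_zero = function(c) {
             if (!is.null(warn_once) && is.null(warn_once$warned)) {
               warn_once$warned <- TRUE
               warning(sprintf("filter '%s': %s; record treated as not passing",
                               filter$text, conditionMessage(c)), call. = FALSE)
             }
             FALSE
           })
}
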