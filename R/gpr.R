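#' Parse a Gene-Protein-Reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which \code{and}
#' encodes an enzyme complex (all subunits required) and \code{or} encodes
#' isozymes (any gene suffices). The parser honours parentheses and the
#' standard operator precedence: \code{and} binds tighter than \code{or}, so
#' \code{"g1 and g2 or g3"} parses as \code{OR(AND(g1, g2), g3)}. Operator
#' tokens are case-insensitive; gene identifiers keep their case.
#'
#' The returned tree is a nested list. Leaves are
#' \code{list(op = "gene", gene = <id>)}; internal nodes are
#' \code{list(op = "and"|"or", args = list(...))} with n-ary, flattened
#' children (\code{a and b and c} is a single \code{and} node with three
#' arguments).
#'
#' @param text a single non-empty string over gene ids, \code{and}, \code{or}
#'   and parentheses.
#' @return an object of class \code{gpr_rule}.
#' @examples
#' r <- parse_gpr("(g1 and g2) or g3")
#' gpr_to_string(r)
#' evaluate_gpr(r, c(g1 = 2, g2 = 3, g3 = 1))
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("GPR rule must be a single non-empty string")
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks$type))
    stop(sprintf("GPR parse error: unexpected token '%s' at position %d in \"%s\"",
                 st$toks$value[st$pos], st$toks$at[st$pos], text))
  class(tree) <- "gpr_rule"
  tree
}

gpr_tokenize <- function(text) {
  type <- character(0); value <- character(0); at <- integer(0)
  chars <- strsplit(text, "")[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); value <- c(value, ch); at <- c(at, i)
      i <- i + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    if (lw == "and" || lw == "or") {
      type <- c(type, lw); value <- c(value, word)
    } else {
      type <- c(type, "gene"); value <- c(value, word)
    }
    at <- c(at, i)
    i <- j
  }
  list(type = type, value = value, at = at)
}

gpr_peek <- function(st) if (st$pos <= length(st$toks$type)) st$toks$type[st$pos] else ""

gpr_parse_or <- function(st, text) {
  args <- list(gpr_parse_and(st, text))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, text)))
  }
  gpr_node("or", args)
}

gpr_parse_and <- function(st, text) {
  args <- list(gpr_parse_atom(st, text))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st, text)))
  }
  gpr_node("and", args)
}

gpr_parse_atom <- function(st, text) {
  tp <- gpr_peek(st)
  if (tp == "gene") {
    g <- st$toks$value[st$pos]
    st$pos <- st$pos + 1L
    return(list(op = "gene", gene = g))
  }
  if (tp == "(") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    if (gpr_peek(st) != ")")
      stop(sprintf("GPR parse error: unbalanced parenthesis opened at position %d in \"%s\"",
                   open_at, text))
    st$pos <- st$pos + 1L
    return(inner)
  }
  pos <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else nchar(text) + 1L
  stop(sprintf("GPR parse error: expected gene or '(' at position %d in \"%s\"", pos, text))
}

# collapse single-child nodes, flatten nested same-operator children
gpr_node <- function(op, args) {
  if (length(args) == 1L) return(args[[1L]])
  flat <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  list(op = op, args = flat)
}

#' Serialize a GPR tree back to rule text
#'
#' Inverse of [parse_gpr()]: `parse_gpr(gpr_to_string(t))` yields a tree
#' equivalent to `t`. `and` arguments that are themselves `or` nodes are
#' parenthesised to preserve precedence.
#'
#' @param rule a `gpr_rule` tree.
#' @return a single string.
#' @export
gpr_to_string <- function(rule) {
  ser <- function(node) {
    if (node$op == "gene") return(node$gene)
    parts <- vapply(node$args, function(a) {
      s <- ser(a)
      if (node$op == "and" && !is.null(a$op) && a$op == "or") paste0("(", s, ")") else s
    }, character(1))
    paste(parts, collapse = paste0(" ", node$op, " "))
  }
  ser(unclass(rule))
}

#' Genes referenced by a GPR tree
#' @param rule a `gpr_rule`.
#' @return character vector of unique gene ids, in first-appearance order.
#' @export
gpr_genes <- function(rule) {
  acc <- character(0)
  walk <- function(node) {
    if (node$op == "gene") acc[[length(acc) + 1L]] <<- node$gene
    else lapply(node$args, walk)
    invisible(NULL)
  }
  walk(unclass(rule))
  unique(acc)
}

#' Evaluate a GPR rule on expression values
#'
#' Implements the activity-score semantics used throughout the package:
#' an \code{and} node takes the \emph{minimum} of its children (complex
#' limited by its scarcest subunit), an \code{or} node takes the \emph{sum}
#' (isozyme activities add). Genes absent from \code{expression} are pruned
#' from the rule before evaluation: an \code{or} loses a summand, an
#' \code{and} loses an argument. If nothing measurable remains the result is
#' \code{NA} (undefined), which is deliberately distinct from zero.
#'
#' @param rule a `gpr_rule` tree (see [parse_gpr()]).
#' @param expression named numeric vector of non-negative expression values;
#'   names are gene ids. Unnamed genes count as unmeasured.
#' @return a single non-negative number, or `NA_real_` if every leaf of the
#'   rule is unmeasured.
#' @examples
#' evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 2, g2 = 3))  # min -> 2
#' evaluate_gpr(parse_gpr("g1 or g2"), c(g1 = 2, g2 = 3))   # sum -> 5
#' @export
evaluate_gpr <- function(rule, expression) {
  stopifnot(is.numeric(expression))
  if (any(!is.finite(expression)) || any(expression < 0))
    stop("expression values must be finite and non-negative")
  ev <- function(node) {
    if (node$op == "gene") {
      if (node$gene %in% names(expression)) return(unname(expression[[node$gene]]))
      return(NA_real_)
    }
    vals <- vapply(node$args, ev, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (node$op == "and") min(vals) else sum(vals)
  }
  ev(unclass(rule))
}

# Vectorised evaluation across spots: `cols` is a named list mapping gene id
# to a numeric vector (one value per spot). Returns a vector or NULL when the
# whole rule is unmeasured. Same pruning semantics as evaluate_gpr().
gpr_evaluate_columns <- function(rule, cols) {
  ev <- function(node) {
    if (node$op == "gene") return(cols[[node$gene]])
    vals <- lapply(node$args, ev)
    vals <- vals[!vapply(vals, is.null, logical(1))]
    if (length(vals) == 0L) return(NULL)
    if (node$op == "and") Reduce(pmin, vals) else Reduce(`+`, vals)
  }
  ev(unclass(rule))
}
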