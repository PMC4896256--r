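#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules link genes to reactions: \code{AND} denotes an enzyme complex
#' (all subunits required), \code{OR} denotes isozymes (any gene suffices).
#' The grammar follows the common SBML-FBC convention: \code{AND} binds
#' tighter than \code{OR}, both are left-associative and case-insensitive,
#' and parentheses override precedence. \code{&}/\code{|} are accepted as
#' synonyms.
#'
#' @param text a single GPR string, e.g. \code{"(g1 AND g2) OR g3"}.
#' @return an object of class \code{gpr}: a tree whose leaves are gene
#'   identifiers and whose internal nodes are \code{and}/\code{or} with at
#'   least two children.
#' @examples
#' parse_gpr("argD OR astC OR gabT OR puuE")
#' parse_gpr("(g1 AND g2) OR g3")
#' @seealso [format_gpr()], [gene_set_expression()]
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("GPR text must be a single non-empty string", call. = FALSE)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st)
  if (st$pos <= nrow(st$toks))
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 st$toks$at[st$pos], st$toks$value[st$pos]), call. = FALSE)
  class(node) <- "gpr"
  node
}

# token table: type in {gene, and, or, lparen, rparen}, value, at (1-based char offset)
gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  type <- character(0); value <- character(0); at <- integer(0)
  i <- 1L
  is_word <- function(ch) grepl("[A-Za-z0-9_.:-]", ch)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "(") { type <- c(type, "lparen"); value <- c(value, "("); at <- c(at, i); i <- i + 1L; next }
    if (ch == ")") { type <- c(type, "rparen"); value <- c(value, ")"); at <- c(at, i); i <- i + 1L; next }
    if (ch == "&") { type <- c(type, "and"); value <- c(value, "&"); at <- c(at, i); i <- i + if (i < n && chars[i + 1L] == "&") 2L else 1L; next }
    if (ch == "|") { type <- c(type, "or"); value <- c(value, "|"); at <- c(at, i); i <- i + if (i < n && chars[i + 1L] == "|") 2L else 1L; next }
    if (is_word(ch)) {
      j <- i
      while (j <= n && is_word(chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      tp <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
      type <- c(type, tp); value <- c(value, word); at <- c(at, i)
      i <- j; next
    }
    stop(sprintf("GPR parse error at position %d: unexpected character '%s'", i, ch),
         call. = FALSE)
  }
  data.frame(type = type, value = value, at = at, stringsAsFactors = FALSE)
}

gpr_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$type[st$pos] else "eof"

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tp <- gpr_peek(st)
  if (tp == "gene") {
    g <- st$toks$value[st$pos]
    st$pos <- st$pos + 1L
    return(list(gene = g))
  }
  if (tp == "lparen") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st)
    if (gpr_peek(st) != "rparen")
      stop(sprintf("GPR parse error: unbalanced '(' at position %d", open_at), call. = FALSE)
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tp == "eof")
    stop("GPR parse error: unexpected end of rule", call. = FALSE)
  stop(sprintf("GPR parse error at position %d: unexpected '%s'",
               st$toks$at[st$pos], st$toks$value[st$pos]), call. = FALSE)
}

#' Format a GPR tree back to text
#'
#' Inverse of [parse_gpr()] up to whitespace: \code{parse_gpr(format_gpr(x))}
#' reproduces \code{x}. Parentheses are emitted only where precedence
#' requires them (around \code{OR} groups nested in \code{AND}).
#'
#' @param gpr a \code{gpr} tree.
#' @return a single string.
#' @export
format_gpr <- function(gpr) {
  fmt <- function(node, parent_op) {
    if (!is.null(node$gene)) return(node$gene)
    sep <- if (node$op == "and") " AND " else " OR "
    inner <- vapply(node$args, fmt, character(1), parent_op = node$op)
    out <- paste(inner, collapse = sep)
    if (node$op == "or" && identical(parent_op, "and")) paste0("(", out, ")") else out
  }
  fmt(unclass(gpr), NULL)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", format_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR tree
#'
#' @param gpr a \code{gpr} tree.
#' @return character vector of unique gene identifiers, in first-appearance order.
#' @export
gpr_genes <- function(gpr) {
  walk <- function(node) {
    if (!is.null(node$gene)) return(node$gene)
    unlist(lapply(node$args, walk))
  }
  unique(walk(unclass(gpr)))
}

# shared min/max recursion used for both expression and variance
gpr_fold <- function(node, value_of) {
  if (!is.null(node$gene)) return(value_of(node$gene))
  vals <- vapply(node$args, gpr_fold, numeric(1), value_of = value_of)
  if (node$op == "and") min(vals) else max(vals)
}
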