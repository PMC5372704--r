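# Gene-protein-reaction rules.
#
# Grammar: identifiers, AND, OR (case-insensitive), parentheses. NOT is not
# part of GEM practice and is rejected. An empty rule means the reaction has
# no gene requirement, so no knockout can silence it.

.gpr_tokenize <- function(gpr) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, gpr)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(gpr, gregexpr(pat, gpr))[[1]]
  toks
}

# Recursive-descent parser producing a nested list AST:
#   list(op = "and"/"or", args = list(...)) or list(op = "gene", id = "g").
.gpr_parse <- function(gpr) {
  toks <- .gpr_tokenize(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  fail <- function(msg) {
    stop("GPR parse error at token ", pos, " ('", peek(), "') in: ", gpr,
         " (", msg, ")", call. = FALSE)
  }

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (t == "(") {
      take()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      take()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or", "not"))
      fail("expected gene identifier")
    take()
    list(op = "gene", id = t)
  }

  if (length(toks) == 0) return(NULL)
  node <- parse_or()
  if (!is.na(peek())) fail("trailing tokens")
  node
}

.gpr_eval_node <- function(node, ko) {
  switch(node$op,
         gene = !(node$id %in% ko),
         and = all(vapply(node$args, .gpr_eval_node, logical(1), ko = ko)),
         or = any(vapply(node$args, .gpr_eval_node, logical(1), ko = ko)),
         stop("corrupt GPR AST"))
}

.gpr_collect_genes <- function(node) {
  if (is.null(node)) return(character(0))
  if (node$op == "gene") return(node$id)
  unique(unlist(lapply(node$args, .gpr_collect_genes)))
}

#' Evaluate a gene-protein-reaction rule under a knockout
#'
#' Knocked-out genes are treated as FALSE and all other genes as TRUE; the
#' reaction is active iff the boolean expression evaluates to TRUE. An empty
#' rule is always active.
#'
#' @param gpr rule string (identifiers, \code{and}, \code{or}, parentheses;
#'   keywords case-insensitive), or \code{""}/\code{NA} for no association.
#' @param knocked_out character vector of knocked-out gene ids.
#' @return \code{TRUE} if the reaction remains active.
#' @examples
#' evaluate_gpr("g1 and g2", "g1")  # FALSE
#' evaluate_gpr("g1 or g2", "g1")   # TRUE
#' evaluate_gpr("", "g1")           # TRUE
#' @export
evaluate_gpr <- function(gpr, knocked_out = character(0)) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(TRUE)
  node <- .gpr_parse(gpr)
  .gpr_eval_node(node, knocked_out)
}

#' Genes referenced by a GPR rule
#' @param gpr rule string.
#' @return Character vector of gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  .gpr_collect_genes(.gpr_parse(gpr))
}
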