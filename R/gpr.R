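#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `and`
#' (enzyme complex: all subunits required) and `or` (isozymes: any suffices),
#' e.g. `"(psaA and psaB) or psaX"`. Operators are case-insensitive; `&`/`|`
#' are accepted as synonyms. An empty rule parses to `NULL`.
#'
#' @param rule character scalar; the rule text (may be `""` or `NA`).
#' @return A parse tree: `NULL` for an empty rule, or a nested list with
#'   elements `op` (one of `"gene"`, `"and"`, `"or"`) and either `id`
#'   (for `op = "gene"`) or `args` (a list of subtrees).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule)) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (!nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule '", rule, "': unexpected token '",
         st$toks[st$pos], "'", call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(rule) {
  # split on parens and whitespace, keeping parens as tokens
  rule <- gsub("([()])", " \\1 ", rule)
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR rule: unexpected end of input", call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("malformed GPR rule: missing closing parenthesis", call. = FALSE)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or"))
    stop("malformed GPR rule: unexpected token '", tok, "'", call. = FALSE)
  st$pos <- st$pos + 1L
  list(op = "gene", id = tok)
}

#' Genes referenced by a GPR parse tree
#' @param tree a tree from [parse_gpr()].
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$id)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR tree over per-gene activity values
#'
#' `and` maps to the minimum of its children (limiting subunit of a complex),
#' `or` to the maximum (best isozyme). Genes absent from `values` contribute
#' the neutral activity `default`.
#'
#' @param tree a tree from [parse_gpr()].
#' @param values named numeric vector of per-gene activities.
#' @param default activity for genes not present in `values` (default 1).
#' @return numeric scalar; `default` for a `NULL` (empty) tree.
#' @export
eval_gpr <- function(tree, values, default = 1) {
  if (is.null(tree)) return(default)
  switch(tree$op,
    gene = if (tree$id %in% names(values)) unname(values[[tree$id]]) else default,
    and  = min(vapply(tree$args, eval_gpr, numeric(1), values = values, default = default)),
    or   = max(vapply(tree$args, eval_gpr, numeric(1), values = values, default = default)),
    stop("invalid GPR node op '", tree$op, "'", call. = FALSE)
  )
}

#' Render a GPR tree back to rule text
#' @param tree a tree from [parse_gpr()].
#' @return character scalar (`""` for `NULL`).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$op == "gene") return(tree$id)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.null(a$op) && a$op %in% c("and", "or")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
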