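#' Resolve an atom selection expression
#'
#' A small selection mini-language over the topology table. An expression
#' is built from clauses of the form `key value [value ...]` joined by
#' `and` / `or`, with parentheses for grouping. Recognised keys:
#'
#' * `chain`   — chain identifier, e.g. `chain A`
#' * `resnum`  — residue number, e.g. `resnum 16` or `resnum 61 62`
#' * `resname` — residue name, e.g. `resname TYL`
#' * `name`    — atom name, e.g. `name NE2`
#' * `element` — element symbol, e.g. `element O`
#'
#' Multiple values after one key match any of them. `and` binds tighter
#' than `or`. Matching is case-sensitive for names, as in PDB files.
#'
#' @param topology A [topology()] tibble (or a `ps_ensemble`, whose
#'   topology is used).
#' @param expression Selection string, e.g. `"resname TYL and name O8"`.
#' @return A `ps_selection`: list with `expression`, integer `indices`
#'   (ascending, unique) and logical `empty`.
#' @examples
#' topo <- topology(c("CA", "NE2"), c("C", "N"), c(16, 16),
#'                  c("HIS", "HIS"), c("A", "A"))
#' resolve_selection(topo, "resnum 16 and name NE2")
#' @export
resolve_selection <- function(topology, expression) {
  if (inherits(topology, "ps_ensemble")) topology <- topology$topology
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, topology)
  if (st$pos <= nrow(st$toks)) {
    abort(paste0(
      "Selection parse error at position ", st$toks$start[st$pos],
      ": unexpected token '", st$toks$text[st$pos], "'."
    ))
  }
  idx <- which(mask)
  structure(
    list(
      expression = expression,
      indices = as.integer(idx),
      empty = length(idx) == 0
    ),
    class = "ps_selection"
  )
}

#' @export
print.ps_selection <- function(x, ...) {
  cat(
    "<ps_selection> '", x$expression, "' -> ", length(x$indices), " atoms",
    if (x$empty) " (EMPTY MATCH)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

# Accept either a ps_selection or a raw expression/index vector, resolving
# against `topo` when needed. Internal convenience used by every module.
as_selection <- function(sel, topo) {
  if (inherits(topo, "ps_ensemble")) topo <- topo$topology
  if (inherits(sel, "ps_selection")) return(sel)
  if (is.character(sel) && length(sel) == 1) {
    return(resolve_selection(topo, sel))
  }
  if (is.numeric(sel)) {
    idx <- sort(unique(as.integer(sel)))
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > nrow(topo))) {
      abort("Selection indices out of range for this topology.")
    }
    return(structure(
      list(
        expression = "<indices>", indices = idx,
        empty = length(idx) == 0
      ),
      class = "ps_selection"
    ))
  }
  abort("Selections must be a ps_selection, an expression string, or indices.")
}

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1 ||
    is.na(expression) || !nzchar(trimws(expression))) {
    abort("Selection expression must be a non-empty string.")
  }
  text <- character()
  start <- integer()
  i <- 1L
  n <- nchar(expression)
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("(", ")")) {
      text <- c(text, ch)
      start <- c(start, i)
      i <- i + 1L
    } else {
      m <- regmatches(
        substr(expression, i, n),
        regexpr("^[^\\s()]+", substr(expression, i, n), perl = TRUE)
      )
      text <- c(text, m)
      start <- c(start, i)
      i <- i + nchar(m)
    }
  }
  tibble(text = text, start = start)
}

sel_keys <- c("chain", "resnum", "resname", "name", "element")

peek <- function(st) {
  if (st$pos > nrow(st$toks)) NA_character_ else st$toks$text[st$pos]
}

parse_or <- function(st, topo) {
  mask <- parse_and(st, topo)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    st$pos <- st$pos + 1L
    mask <- mask | parse_and(st, topo)
  }
  mask
}

parse_and <- function(st, topo) {
  mask <- parse_clause(st, topo)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    st$pos <- st$pos + 1L
    mask <- mask & parse_clause(st, topo)
  }
  mask
}

parse_clause <- function(st, topo) {
  tok <- peek(st)
  if (is.na(tok)) {
    abort("Selection parse error: unexpected end of expression.")
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    mask <- parse_or(st, topo)
    if (is.na(peek(st)) || peek(st) != ")") {
      abort("Selection parse error: missing closing parenthesis.")
    }
    st$pos <- st$pos + 1L
    return(mask)
  }
  key <- tolower(tok)
  if (!key %in% sel_keys) {
    abort(paste0(
      "Selection parse error at position ", st$toks$start[st$pos],
      ": unknown key '", tok, "' (expected one of ",
      paste(sel_keys, collapse = ", "), ")."
    ))
  }
  st$pos <- st$pos + 1L
  vals <- character()
  while (!is.na(peek(st)) &&
    !tolower(peek(st)) %in% c("and", "or", sel_keys) &&
    !peek(st) %in% c("(", ")")) {
    vals <- c(vals, peek(st))
    st$pos <- st$pos + 1L
  }
  if (length(vals) == 0) {
    abort(paste0(
      "Selection parse error at position ",
      if (st$pos > nrow(st$toks)) nchar("") else st$toks$start[st$pos],
      ": key '", key, "' needs at least one value."
    ))
  }
  switch(key,
    chain = topo$chain_id %in% vals,
    resnum = {
      nums <- suppressWarnings(as.integer(vals))
      if (anyNA(nums)) abort("resnum values must be integers.")
      topo$residue_number %in% nums
    },
    resname = topo$residue_name %in% vals,
    name = topo$atom_name %in% vals,
    element = topo$element %in% vals
  )
}
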