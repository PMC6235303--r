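#' Select atoms by a small expression grammar
#'
#' The grammar supports keywords `species`, `name`, `resname`, `resid` and
#' `element`, each followed by one or more values, combined with `and`, `or`,
#' `not` and parentheses.  `resid` accepts single numbers or `lo:hi` ranges.
#' Species values must be one of `SOLUTE WATER CROWDER CATION ANION`.
#'
#' @param topology a [make_topology()] topology.
#' @param expression selection string, e.g.
#'   `"species WATER and name O"` or `"name OP1 OP2"`.
#' @return sorted integer vector of atom indices (possibly empty).
#' @examples
#' ## top <- read_topology(...)
#' ## select_atoms(top, "species SOLUTE and not element H")
#' @export
select_atoms <- function(topology, expression) {
  toks <- .sel_tokens(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  res <- .sel_or(st, topology)
  if (st$i <= length(st$toks))
    stop("malformed selection near '", st$toks[st$i], "'")
  which(res)
}

.sel_tokens <- function(expression) {
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  if (!length(toks) || !nzchar(toks[1])) stop("empty selection expression")
  toks
}

.sel_peek <- function(st) if (st$i <= length(st$toks)) st$toks[st$i] else NA_character_

.sel_or <- function(st, top) {
  res <- .sel_and(st, top)
  while (identical(tolower(.sel_peek(st)), "or")) {
    st$i <- st$i + 1L
    res <- res | .sel_and(st, top)
  }
  res
}

.sel_and <- function(st, top) {
  res <- .sel_unary(st, top)
  while (identical(tolower(.sel_peek(st)), "and")) {
    st$i <- st$i + 1L
    res <- res & .sel_unary(st, top)
  }
  res
}

.sel_unary <- function(st, top) {
  tok <- .sel_peek(st)
  if (is.na(tok)) stop("unexpected end of selection expression")
  if (tolower(tok) == "not") {
    st$i <- st$i + 1L
    return(!.sel_unary(st, top))
  }
  if (tok == "(") {
    st$i <- st$i + 1L
    res <- .sel_or(st, top)
    if (!identical(.sel_peek(st), ")")) stop("missing ')' in selection")
    st$i <- st$i + 1L
    return(res)
  }
  .sel_primary(st, top)
}

.sel_values <- function(st) {
  vals <- character()
  stopwords <- c("and", "or", "not", "(", ")")
  repeat {
    tok <- .sel_peek(st)
    if (is.na(tok) || tolower(tok) %in% stopwords) break
    vals <- c(vals, tok)
    st$i <- st$i + 1L
  }
  if (!length(vals)) stop("selection keyword without a value")
  vals
}

.sel_primary <- function(st, top) {
  key <- tolower(.sel_peek(st))
  st$i <- st$i + 1L
  a <- top$atoms
  switch(key,
    species = {
      vals <- toupper(.sel_values(st))
      bad <- setdiff(vals, SPECIES_LEVELS)
      if (length(bad))
        stop("unknown species token(s): ", paste(bad, collapse = ", "))
      a$species %in% vals
    },
    name = a$name %in% .sel_values(st),
    resname = a$resname %in% .sel_values(st),
    element = toupper(a$element) %in% toupper(.sel_values(st)),
    resid = {
      vals <- .sel_values(st)
      keep <- rep(FALSE, nrow(a))
      for (v in vals) {
        if (grepl(":", v, fixed = TRUE)) {
          rng <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
          if (length(rng) != 2 || anyNA(rng)) stop("bad resid range '", v, "'")
          keep <- keep | (a$resid >= rng[1] & a$resid <= rng[2])
        } else {
          ri <- suppressWarnings(as.integer(v))
          if (is.na(ri)) stop("bad resid value '", v, "'")
          keep <- keep | a$resid == ri
        }
      }
      keep
    },
    stop("unknown selection keyword '", key, "'")
  )
}
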