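#' Select atoms with a small expression language
#'
#' Supported primaries: \code{chain <id>}, \code{resid <n>} or
#' \code{resid <a>:<b>}, \code{name <atom name>}, \code{element <symbol>},
#' \code{group <membrane|water|ion|protein|protein:X>}. Primaries combine
#' with \code{and}, \code{or}, \code{not} and parentheses; \code{all}
#' matches everything. The result is deterministic and ordered by atom
#' index.
#'
#' @param top a \code{topology} or \code{trajectory}
#' @param expr selection expression, e.g. \code{"chain A and name CA"}
#' @return integer vector of atom indices (class \code{"atom_selection"})
#' @examples
#' top <- topology(data.frame(serial = 1:2, name = c("CA", "CB"),
#'   element = "C", res_name = "ALA", res_seq = 1L, chain_id = "A"))
#' select_atoms(top, "name CA")
#' @export
select_atoms <- function(top, expr) {
  if (inherits(top, "trajectory")) top <- top$topology
  stopifnot(inherits(top, "topology"), is.character(expr), length(expr) == 1L)
  tokens <- scan(text = gsub("([()])", " \\1 ", expr), what = character(),
                 quiet = TRUE)
  if (length(tokens) == 0L) stop("select_atoms(): empty expression")
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() {
    t <- peek()
    if (is.na(t)) stop("select_atoms(): unexpected end of expression")
    pos <<- pos + 1L
    t
  }
  parse_primary <- function() {
    t <- take()
    if (t == "(") {
      m <- parse_or()
      if (!identical(peek(), ")")) stop("select_atoms(): missing ')'")
      take()
      return(m)
    }
    if (t == "not") return(!parse_primary())
    if (t == "all") return(rep(TRUE, nrow(top)))
    arg <- take()
    switch(t,
      chain = top$chain_id == arg,
      name = top$name == arg,
      element = top$element == arg,
      group = {
        if (arg == "protein") {
          !is.na(top$group) & startsWith(top$group, "protein:")
        } else {
          !is.na(top$group) & top$group == arg
        }
      },
      resid = {
        parts <- strsplit(arg, "[:-]")[[1L]]
        rng <- suppressWarnings(as.integer(parts))
        if (anyNA(rng) || !length(rng) %in% 1:2) {
          stop("select_atoms(): bad residue range '", arg, "'")
        }
        if (length(rng) == 1L) rng <- c(rng, rng)
        top$res_seq >= rng[1L] & top$res_seq <= rng[2L]
      },
      stop("select_atoms(): unknown keyword '", t, "'")
    )
  }
  parse_and <- function() {
    m <- parse_primary()
    while (identical(peek(), "and")) {
      take()
      m <- m & parse_primary()
    }
    m
  }
  parse_or <- function() {
    m <- parse_and()
    while (identical(peek(), "or")) {
      take()
      m <- m | parse_and()
    }
    m
  }
  mask <- parse_or()
  if (pos <= length(tokens)) {
    stop("select_atoms(): trailing tokens from '", tokens[pos], "'")
  }
  structure(which(mask), class = "atom_selection")
}

#' Validate an explicit atom selection
#' @param indices integer atom indices
#' @param top topology the indices refer to
#' @return class \code{"atom_selection"} integer vector
#' @export
atom_selection <- function(indices, top) {
  if (inherits(top, "trajectory")) top <- top$topology
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("atom_selection(): duplicate indices")
  if (length(indices) > 0 &&
      (min(indices) < 1L || max(indices) > nrow(top))) {
    stop("atom_selection(): index out of range")
  }
  structure(sort(indices), class = "atom_selection")
}
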