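#' Parse a reaction equation string
#'
#' Equations use the dialect \code{"1 a + 2 b -> 1 c"} (irreversible) or
#' \code{"1 a + 2 b <-> 1 c"} (reversible). Coefficients are optional and
#' default to 1; an empty side denotes an exchange with the environment.
#'
#' @param eq character scalar.
#' @return list with \code{stoich} (named numeric, negative = consumed) and
#'   \code{reversible} (logical).
#' @export
#' @examples
#' parse_equation("1 co2_e <-> 1 co2_c")
parse_equation <- function(eq) {
  stopifnot(is.character(eq), length(eq) == 1L)
  reversible <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) > 2L || !grepl("->", eq, fixed = TRUE))
    stop("malformed reaction equation: ", eq)
  if (length(sides) == 1L) sides <- c(sides, "")
  acc <- numeric(0)
  add_side <- function(acc, side, sign) {
    side <- trimws(side)
    if (side == "") return(acc)
    for (term in strsplit(side, "+", fixed = TRUE)[[1]]) {
      parts <- strsplit(trimws(term), "[[:space:]]+")[[1]]
      parts <- parts[parts != ""]
      if (length(parts) == 0L) next
      if (length(parts) == 1L) {
        coef <- 1; met <- parts[1]
      } else if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient in term '", term, "'")
        met <- parts[2]
      } else stop("bad term '", term, "' in equation: ", eq)
      acc[met] <- (if (met %in% names(acc)) acc[[met]] else 0) + sign * coef
    }
    acc
  }
  acc <- add_side(acc, sides[1], -1)
  acc <- add_side(acc, sides[2], +1)
  acc <- acc[acc != 0]
  if (length(acc) == 0L) stop("empty stoichiometry in equation: ", eq)
  list(stoich = acc, reversible = reversible)
}

#' Format a stoichiometry vector as an equation string
#' @param stoich named numeric vector, negative coefficients are substrates.
#' @param reversible logical; use \code{"<->"} when TRUE.
#' @return character scalar.
#' @keywords internal
format_equation <- function(stoich, reversible = TRUE) {
  stoich <- stoich[stoich != 0]
  ids <- names(stoich)[order(names(stoich))]
  stoich <- stoich[ids]
  fmt <- function(v) paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
  lhs <- fmt(stoich[stoich < 0])
  rhs <- fmt(stoich[stoich > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

## carbon atoms from a molecular formula ("C6H13O9P" -> 6); tokens such as
## "X" (macromolecular placeholder) or "" yield 0
count_carbon <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(0)
    m <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    tot <- 0
    for (tok in m) {
      el <- gsub("[0-9]", "", tok)
      if (el == "C") {
        num <- gsub("[^0-9]", "", tok)
        tot <- tot + if (nzchar(num)) as.numeric(num) else 1
      }
    }
    tot
  }, numeric(1), USE.NAMES = FALSE)
}
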