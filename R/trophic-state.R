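#' Trophic state levels
#'
#' Lake trophic state is represented throughout the package as an ordered
#' factor with four levels, from nutrient-poor to nutrient-rich:
#' oligotrophic < mesotrophic < eutrophic < hypereutrophic.
#'
#' @return Character vector of the four level names, in increasing order of
#'   nutrient enrichment.
#' @export
#' @examples
#' trophic_levels()
trophic_levels <- function() {
  c("oligotrophic", "mesotrophic", "eutrophic", "hypereutrophic")
}

#' Coerce to a trophic state factor
#'
#' Accepts ordinal codes 1--4, level names (case-insensitive, lowercase on
#' output), or an existing factor, and returns an ordered factor on the four
#' canonical levels.
#'
#' @param x Vector of codes (1--4), level names, or a factor.
#' @return Ordered factor with levels `trophic_levels()`.
#' @export
#' @examples
#' as_trophic_state(c(1, 4, 2))
#' as_trophic_state(c("eutrophic", "oligotrophic"))
as_trophic_state <- function(x) {
  lv <- trophic_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & (x < 1 | x > 4 | x != round(x))
    if (any(bad)) {
      stop("trophic state codes must be integers in 1..4; offending value: ",
           x[bad][1L], call. = FALSE)
    }
    return(factor(lv[as.integer(x)], levels = lv, ordered = TRUE))
  }
  if (is.character(x)) {
    xl <- tolower(trimws(x))
    num <- suppressWarnings(as.integer(xl))
    xl[!is.na(num)] <- lv[num[!is.na(num)]]
    bad <- !is.na(xl) & !(xl %in% lv)
    if (any(bad)) {
      stop("unknown trophic state label: '", x[bad][1L], "'", call. = FALSE)
    }
    return(factor(xl, levels = lv, ordered = TRUE))
  }
  stop("cannot interpret object of class '", class(x)[1L],
       "' as trophic states", call. = FALSE)
}

# integer codes 1..4 (NA preserved); input may be factor, name or code
.state_code <- function(x) {
  as.integer(as_trophic_state(x))
}
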