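#' Rule patterns with wildcards
#'
#' A pattern fixes some of the ten strategy bits and leaves the rest as
#' wildcards (`NA`).  An optional constraint bounds how many wildcard
#' positions may take the value 0 in a matching strategy; this encodes the
#' "h-score must keep increasing" restriction on the cooperator families.
#'
#' @param slots ten values in `{0, 1, NA}` (NA = wildcard), or a 10-character
#'   string over `0`, `1`, `*`.
#' @param max_zero_wildcards maximum number of wildcard slots a matching
#'   strategy may set to 0 (`Inf` for no constraint).
#' @param name optional label.
#' @return an object of class `ir_pattern`.
#' @examples
#' p <- rule_pattern("10111*0*0*", max_zero_wildcards = 1)  # C1-4 family
#' match_pattern(ir_catalog()$strategies$standing, p)
#' @export
rule_pattern <- function(slots, max_zero_wildcards = Inf, name = NULL) {
  if (is.character(slots) && length(slots) == 1L) {
    if (nchar(slots) != 10L || grepl("[^01*]", slots))
      stop("pattern string must be ten characters over 0/1/*, got '",
           slots, "'")
    ch <- strsplit(slots, "")[[1L]]
    slots <- rep(NA_integer_, 10L)
    slots[ch != "*"] <- as.integer(ch[ch != "*"])
  }
  slots <- as.integer(slots)
  if (length(slots) != 10L || !all(slots %in% c(0L, 1L, NA_integer_)))
    stop("a pattern needs exactly ten slots, each 0, 1 or NA")
  if (length(max_zero_wildcards) != 1L || is.na(max_zero_wildcards) ||
      max_zero_wildcards < 0)
    stop("max_zero_wildcards must be a single non-negative number")
  names(slots) <- BIT_NAMES
  structure(list(slots = slots, max_zero_wildcards = max_zero_wildcards,
                 name = name),
            class = "ir_pattern")
}

#' @export
format.ir_pattern <- function(x, ...) {
  s <- ifelse(is.na(x$slots), "*", as.character(x$slots))
  paste(s, collapse = "")
}

#' @export
print.ir_pattern <- function(x, ...) {
  cat(sprintf("<pattern %s%s", format(x),
              if (!is.null(x$name)) paste0("  '", x$name, "'") else ""))
  if (is.finite(x$max_zero_wildcards))
    cat(sprintf("  (max %d wildcard(s) = 0)", x$max_zero_wildcards))
  cat(">\n")
  invisible(x)
}

#' Match a strategy against a pattern
#'
#' A strategy matches iff every non-wildcard slot agrees and at most
#' `max_zero_wildcards` of the wildcard slots are 0 in the strategy.
#'
#' @inheritParams encode_strategy
#' @param pattern an `ir_pattern` from [rule_pattern()].
#' @return logical.
#' @export
match_pattern <- function(s, pattern) {
  s <- as_strategy(s)
  if (!inherits(pattern, "ir_pattern"))
    stop("pattern must be built with rule_pattern()")
  fixed <- !is.na(pattern$slots)
  if (!all(s[fixed] == pattern$slots[fixed])) return(FALSE)
  sum(s[!fixed] == 0L) <= pattern$max_zero_wildcards
}

#' Strategies matching a pattern
#'
#' @param pattern an `ir_pattern`.
#' @param within list of `ir_strategy` to search (defaults to the canonical
#'   set).
#' @return the matching subset, as a list of `ir_strategy`.
#' @export
pattern_members <- function(pattern, within = canonical_set()) {
  Filter(function(s) match_pattern(s, pattern), within)
}

#' Catalog of named strategies and literature rule patterns
#'
#' Concrete strategies: image scoring (judge the action only), the standing
#' strategy (justified defection against a bad recipient stays good), and the
#' canonical unconditional cooperator/defector.  Patterns: the leading-eight
#' template from the public-assessment literature, the three cooperator-ESS
#' families C1-4, C5-11, C12-15 (with their wildcard-zero constraints), and
#' the perfect-defector signatures `d10 = d00 = 0` and `c10 = c00 = 0`.
#'
#' @return a list with elements `strategies` (named `ir_strategy` list) and
#'   `patterns` (named `ir_pattern` list).
#' @export
ir_catalog <- function() {
  list(
    strategies = list(
      image_scoring = as_strategy("1011110000"),
      standing      = as_strategy("1011110101"),
      allc          = as_strategy("1111111111"),
      alld          = as_strategy("0000000000")),
    patterns = list(
      leading_eight = rule_pattern("101*1*010*", name = "leading eight"),
      c1_4   = rule_pattern("10111*0*0*", max_zero_wildcards = 1, name = "C1-4"),
      c5_11  = rule_pattern("10111*0*1*", max_zero_wildcards = 2, name = "C5-11"),
      c12_15 = rule_pattern("10110*1*0*", max_zero_wildcards = 1, name = "C12-15"),
      defector_d = rule_pattern("*******0*0", name = "defector d10=d00=0"),
      defector_c = rule_pattern("***0*0****", name = "defector c10=c00=0")))
}

#' The fifteen cooperator-ESS bit patterns
#'
#' Union of the C1-4, C5-11 and C12-15 families restricted to the canonical
#' (discriminator) strategies, with wildcard-zero constraints applied.
#'
#' @return a list of 15 `ir_strategy`, sorted by integer code.
#' @export
cooperator_family <- function() {
  pats <- ir_catalog()$patterns[c("c1_4", "c5_11", "c12_15")]
  members <- unique(unlist(lapply(pats, function(p)
    vapply(pattern_members(p), encode_strategy, 0))))
  lapply(sort(members), decode_strategy)
}
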