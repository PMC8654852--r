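#' @useDynLib privrep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BIT_NAMES <- c("a1", "a0",
               "c11", "c10", "c01", "c00",
               "d11", "d10", "d01", "d00")

#' Construct a moral strategy
#'
#' A strategy in the privately-assessed donation game consists of an action
#' rule pair and two assessment-rule tables.  The action bits `a1`/`a0` say
#' whether the individual cooperates with a recipient it currently deems good
#' (`a1`) or bad (`a0`).  The assessment bits give the new opinion assigned to
#' an observed donor, indexed by the observer's current opinion of the donor
#' (first index) and of the recipient (second index): `c_ij` when the donor
#' cooperated, `d_ij` when it defected.  The opinion of the recipient is never
#' updated.
#'
#' @param a1,a0 action bits (0 or 1).
#' @param c11,c10,c01,c00 assessment bits applied after an observed
#'   cooperation.
#' @param d11,d10,d01,d00 assessment bits applied after an observed defection.
#' @return an object of class `ir_strategy`: a named integer vector of ten
#'   bits in the fixed order `a1,a0,c11,c10,c01,c00,d11,d10,d01,d00`.
#' @examples
#' standing <- strategy(1, 0, 1, 1, 1, 1, 0, 1, 0, 1)
#' encode_strategy(standing)  # 757
#' @export
strategy <- function(a1, a0, c11, c10, c01, c00, d11, d10, d01, d00) {
  bits <- c(a1, a0, c11, c10, c01, c00, d11, d10, d01, d00)
  as_strategy(bits)
}

#' Coerce bits to a strategy
#'
#' @param bits a vector of ten 0/1 values, a 10-character bit string, or an
#'   `ir_strategy`.
#' @return an `ir_strategy`.
#' @export
as_strategy <- function(bits) {
  if (inherits(bits, "ir_strategy")) return(bits)
  if (is.character(bits) && length(bits) == 1L) {
    if (nchar(bits) != 10L || grepl("[^01]", bits))
      stop("strategy bit string must be ten characters of 0/1, got '",
           bits, "'")
    bits <- as.integer(strsplit(bits, "")[[1L]])
  }
  bits <- as.integer(bits)
  if (length(bits) != 10L || anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("a strategy needs exactly ten bits, each 0 or 1")
  names(bits) <- BIT_NAMES
  class(bits) <- "ir_strategy"
  bits
}

#' @export
format.ir_strategy <- function(x, ...) paste(unclass(x), collapse = "")

#' @export
print.ir_strategy <- function(x, ...) {
  cat(sprintf("<strategy %s  code %d>\n", format(x), encode_strategy(x)))
  cat(sprintf("  actions  a = (%d,%d)   [%s]\n", x[["a1"]], x[["a0"]],
              behavioral_class(x)))
  cat(sprintf("  assess C = %s  D = %s\n",
              paste(x[3:6], collapse = ""), paste(x[7:10], collapse = "")))
  invisible(x)
}

#' Integer encoding of a strategy
#'
#' Bit order is `a1,a0,c11,c10,c01,c00,d11,d10,d01,d00` with `a1` most
#' significant, so codes run from 0 (all-zero) to 1023 (all-one).
#'
#' @param s an `ir_strategy` (or anything [as_strategy()] accepts).
#' @return integer in `[0, 1023]`.
#' @export
encode_strategy <- function(s) {
  s <- as_strategy(s)
  sum(as.integer(s) * 2L^(9:0))
}

#' @rdname encode_strategy
#' @param code integer in `[0, 1023]`.
#' @export
decode_strategy <- function(code) {
  if (length(code) != 1L || is.na(code) || code != trunc(code) ||
      code < 0 || code > 1023)
    stop("strategy code must be a single integer in [0, 1023], got ",
         deparse(substitute(code)), " = ", paste(code, collapse = ","))
  code <- as.integer(code)
  as_strategy(bitwAnd(bitwShiftR(code, 9:0), 1L))
}

#' Mirror (good/bad label swap) of a strategy
#'
#' Swapping the labels "good" and "bad" everywhere yields a behaviourally
#' equivalent strategy: `a'_i = a_{1-i}`, `c'_ij = 1 - c_{(1-i)(1-j)}` and
#' `d'_ij = 1 - d_{(1-i)(1-j)}`.  The map is an involution.
#'
#' @inheritParams encode_strategy
#' @return the mirrored `ir_strategy`.
#' @export
mirror_strategy <- function(s) {
  s <- as_strategy(s)
  strategy(a1  = s[["a0"]],        a0  = s[["a1"]],
           c11 = 1L - s[["c00"]],  c10 = 1L - s[["c01"]],
           c01 = 1L - s[["c10"]],  c00 = 1L - s[["c11"]],
           d11 = 1L - s[["d00"]],  d10 = 1L - s[["d01"]],
           d01 = 1L - s[["d10"]],  d00 = 1L - s[["d11"]])
}

#' Behavioural class of a strategy
#'
#' Determined by the action pair alone: `(1,1)` always cooperates (ALLC),
#' `(0,0)` always defects (ALLD), `(1,0)` cooperates with those it deems good
#' (DISCRIMINATOR) and `(0,1)` does the opposite (PARADOXICAL).
#'
#' @inheritParams encode_strategy
#' @return one of `"ALLC"`, `"ALLD"`, `"DISCRIMINATOR"`, `"PARADOXICAL"`.
#' @export
behavioral_class <- function(s) {
  s <- as_strategy(s)
  a <- paste0(s[["a1"]], s[["a0"]])
  switch(a,
         "11" = "ALLC",
         "00" = "ALLD",
         "10" = "DISCRIMINATOR",
         "01" = "PARADOXICAL")
}

#' The 258 behaviourally distinct canonical strategies
#'
#' Of the 1024 raw strategies, unconditional ones (`a1 = a0`) never read an
#' opinion, so their 256 assessment variants each collapse to a single
#' representative; paradoxical strategies are mirrors of discriminators.  What
#' remains is all 256 discriminators plus one canonical ALLC (assessments
#' all 1) and one canonical ALLD (assessments all 0).
#'
#' @return a list of 258 `ir_strategy` objects, ALLC first, ALLD second, then
#'   the 256 discriminators in increasing code order.
#' @export
canonical_set <- function() {
  out <- vector("list", 258L)
  out[[1L]] <- as_strategy(rep(1L, 10L))            # ALLC
  out[[2L]] <- as_strategy(rep(0L, 10L))            # ALLD
  disc <- lapply(0:255, function(k)
    as_strategy(c(1L, 0L, bitwAnd(bitwShiftR(as.integer(k), 7:0), 1L))))
  out[3:258] <- disc
  out
}

#' @rdname canonical_set
#' @return `canonical_codes()`: the integer codes of the canonical set.
#' @export
canonical_codes <- function() vapply(canonical_set(), encode_strategy, 0)

#' Map any raw strategy onto its canonical representative
#'
#' ALLC/ALLD variants map to the canonical unconditional strategy of their
#' class; paradoxical strategies map to their (discriminator) mirror;
#' discriminators map to themselves.
#'
#' @inheritParams encode_strategy
#' @return an `ir_strategy` belonging to [canonical_set()].
#' @export
canonicalize <- function(s) {
  s <- as_strategy(s)
  switch(behavioral_class(s),
         ALLC = as_strategy(rep(1L, 10L)),
         ALLD = as_strategy(rep(0L, 10L)),
         DISCRIMINATOR = s,
         PARADOXICAL = mirror_strategy(s))
}

#' Enumerate and summarise all 1024 raw strategies
#'
#' @return a data.frame with one row per raw strategy: `code`, `bits`,
#'   `class`, and `canonical_code` (the representative under
#'   [canonicalize()]).
#' @export
enumerate_strategies <- function() {
  strat <- lapply(0:1023, decode_strategy)
  data.frame(
    code = 0:1023,
    bits = vapply(strat, format, ""),
    class = vapply(strat, behavioral_class, ""),
    canonical_code = vapply(strat, function(s) encode_strategy(canonicalize(s)), 0),
    stringsAsFactors = FALSE)
}
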