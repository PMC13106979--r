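#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids, one-letter codes, alphabetical
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Pad token used for window positions that fall beyond a protein terminus.
PAD_TOKEN <- "-"

# Internal single-character token for a central citrulline in core/peptide
# strings; exports render it as "R" plus a modification annotation (or the
# inline dialect "R[cit]").
CIT_CHAR <- "r"

#' Largest-remainder rounding of proportions to integer percents
#'
#' Rounds a vector of non-negative weights to integer percentages that sum
#' exactly to `total`. Each value receives its floor; the remaining units go
#' to the entries with the largest fractional remainders (ties broken by
#' original order, deterministically).
#'
#' @param w Non-negative numeric weights (need not sum to 1).
#' @param total Integer total to distribute (default 100).
#' @return Integer vector, same length as `w`, summing to `total`.
#' @export
largest_remainder_percents <- function(w, total = 100L) {
  stopifnot(is.numeric(w), all(w >= 0), sum(w) > 0)
  x <- w / sum(w) * total
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    take <- order(-(x - fl), seq_along(x))[seq_len(rem)]
    fl[take] <- fl[take] + 1
  }
  as.integer(fl)
}

# Run `expr` with a private, seeded RNG stream, restoring the caller's RNG
# state afterwards so package functions have no side effects on .Random.seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Offsets formatted with an explicit sign, as motif positions are usually
# written ("-3", "+1").
format_offset <- function(x) ifelse(x > 0, paste0("+", x), as.character(x))
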