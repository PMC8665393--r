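# Internal helpers shared across modules.

#' Study days belonging to a phase
#'
#' The study-day axis is anchored at the first chemotherapy administration
#' (C1D1 = day 0). The prechemotherapy phase spans days -7..-1 (7 days) and
#' the postchemotherapy phase days 1..14 (14 days); day 0 itself belongs to
#' neither phase.
#'
#' @param phase `"pre"` or `"post"`.
#' @return Integer vector of study days in the phase.
#' @export
#' @examples
#' phase_days("pre")
#' length(phase_days("post"))
phase_days <- function(phase = c("pre", "post")) {
  phase <- match.arg(phase)
  if (phase == "pre") -7L:-1L else 1L:14L
}

#' @keywords internal
study_day_range <- function() c(-7L, 14L)

# round() uses round-half-even; printed report percentages and day counts
# use the conventional half-up rule instead.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Integer percentages that sum to 100 via the largest-remainder method.
# Ties in the fractional remainders are broken in favour of later
# categories, so the canonical (FULL, PARTIAL, NONE) ordering favours the
# least-complete category.
pct_integer <- function(counts) {
  total <- sum(counts)
  stopifnot(total > 0)
  pct <- 100 * counts / total
  base <- floor(pct)
  rem <- pct - base
  short <- 100L - as.integer(round(sum(base)))
  if (short > 0) {
    take <- order(-rem, -seq_along(rem))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  out <- as.integer(base)
  names(out) <- names(counts)
  out
}

st_stop <- function(..., class = "steptrack_error") {
  stop(errorCondition(paste0(...), class = c(class, "steptrack_error")))
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

# Integer parse: "" / NA -> NA (missing), any other non-integral or
# non-numeric token -> NaN (malformed), so callers can tell the two apart.
parse_int <- function(x) {
  x[is.na(x)] <- ""
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[is.na(out) & x != ""] <- NaN
  out[is.finite(out) & out != floor(out)] <- NaN
  out[x == ""] <- NA_real_
  out
}
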