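#' Isochore family definitions
#'
#' The five classical GC-content families used both to simulate domains and to
#' classify windows: L1 (<37% GC), L2 (37--41%), H1 (41--46%), H2 (46--53%)
#' and H3 (>53%). Interior boundaries are fixed by that definition; the outer
#' limits of L1 and H3 (needed only when *sampling* a target GC) default to
#' 0.30 and 0.63 and are configurable. Each family carries a sampling weight,
#' the genome-fraction mass with which domains are assigned to it (defaults
#' 22.8, 33.2, 22.7, 11.2, 3.01 for L1..H3, normalized at use).
#'
#' @param gc_min Lower GC limit of L1 used for sampling (fraction).
#' @param gc_max Upper GC limit of H3 used for sampling (fraction).
#' @param weights Named numeric vector of non-negative sampling masses for
#'   L1, L2, H1, H2, H3 (need not sum to 1).
#' @return A data frame with columns `name`, `gc_low`, `gc_high`, `weight`,
#'   one row per family, ordered L1..H3.
#' @examples
#' isochore_families()
#' @export
isochore_families <- function(gc_min = 0.30, gc_max = 0.63,
                              weights = c(L1 = 22.8, L2 = 33.2, H1 = 22.7,
                                          H2 = 11.2, H3 = 3.01)) {
  nm <- c("L1", "L2", "H1", "H2", "H3")
  stopifnot(is.numeric(gc_min), is.numeric(gc_max))
  if (!(gc_min < 0.37)) stop("gc_min must be below 0.37 (the L1/L2 boundary)")
  if (!(gc_max > 0.53)) stop("gc_max must be above 0.53 (the H2/H3 boundary)")
  w <- weights[nm]
  if (anyNA(w) || any(w < 0)) stop("weights must be non-negative and named L1, L2, H1, H2, H3")
  lo <- c(gc_min, 0.37, 0.41, 0.46, 0.53)
  hi <- c(0.37, 0.41, 0.46, 0.53, gc_max)
  data.frame(name = nm, gc_low = lo, gc_high = hi, weight = unname(w),
             stringsAsFactors = FALSE)
}

#' Classify a GC fraction into an isochore family
#'
#' Bands are half-open `[low, high)`: L1 if gc < 0.37; L2 in \[0.37, 0.41);
#' H1 in \[0.41, 0.46); H2 in \[0.46, 0.53); H3 if gc >= 0.53. So a window at
#' GC 0.52999 is H2 while one at 0.53001 is H3.
#'
#' @param gc Numeric vector of GC fractions in \[0, 1\].
#' @return Character vector of family names.
#' @examples
#' classify_family(c(0.52999, 0.53001, 0.41))
#' @export
classify_family <- function(gc) {
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc must lie in [0, 1]")
  nm <- c("L1", "L2", "H1", "H2", "H3")
  nm[findInterval(gc, c(0.37, 0.41, 0.46, 0.53)) + 1L]
}

#' Sample isochore family names by weight
#'
#' Draws family names with probability proportional to their sampling weight,
#' optionally excluding one family (used to keep adjacent simulated domains in
#' different families).
#'
#' @param n Number of draws.
#' @param exclude Optional family name to exclude from the draw.
#' @param families Family table from [isochore_families()].
#' @return Character vector of `n` family names.
#' @examples
#' set.seed(1)
#' table(sample_family(1000))
#' @export
sample_family <- function(n = 1, exclude = NULL, families = isochore_families()) {
  w <- setNames(families$weight, families$name)
  if (!is.null(exclude)) {
    if (!exclude %in% names(w)) stop("unknown family in 'exclude': ", exclude)
    w[exclude] <- 0
  }
  if (sum(w) <= 0 || sum(w > 0) < 1)
    stop("no family has positive weight after exclusion")
  sample(names(w), n, replace = TRUE, prob = w)
}

# family sequence of length k with no two consecutive equal
sample_family_run <- function(k, families = isochore_families()) {
  out <- character(k)
  out[1] <- sample_family(1, families = families)
  if (k > 1) {
    if (sum(families$weight > 0) < 2)
      stop("need at least two families with positive weight for adjacent-distinct assignment")
    for (i in 2:k) out[i] <- sample_family(1, exclude = out[i - 1], families = families)
  }
  out
}
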