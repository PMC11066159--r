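# U3:C3 discrimination-ratio statistic, its LOD-censored floor, and the
# inosine-detectability model.

# Half-up rounding with a guard against binary representation error:
# shares computed from decimal efficiencies (e.g. 6.6/17.6 = 37.5 exactly)
# can land a hair below the true half in double precision, which would
# otherwise round the wrong way.
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

new_discrimination_ratio <- function(raw_fraction, is_floor) {
  u <- as.integer(round_half_up(100 * raw_fraction))
  structure(
    list(u_share = u, c_share = 100L - u, is_floor = is_floor,
         raw_fraction = raw_fraction),
    class = "discrimination_ratio"
  )
}

#' U3:C3 discrimination ratio
#'
#' How often, out of 100 orthogonal-tRNA-directed incorporation events, the
#' tRNA selects the U-ending rather than the C-ending codon:
#' \deqn{RE_U / (RE_U + RE_C),}
#' expressed as integer shares summing to 100 (round-half-up on the U
#' share). Because the statistic is a ratio of efficiencies of the same
#' tRNA, aminoacylation level and competition against endogenous tRNAs
#' cancel, making tRNA species comparable regardless of absolute
#' reassignment: it is invariant under common scaling of both inputs.
#'
#' Both inputs must be detected (not censored); when the C-ending efficiency
#' is below the limit of detection use [discrimination_floor()].
#'
#' @param re_u Reassignment efficiency of the U-ending codon (percent, > 0).
#' @param re_c Reassignment efficiency of the C-ending codon (percent, >= 0).
#' @return Object of class `discrimination_ratio`: `u_share`, `c_share`
#'   (integers summing to 100), `is_floor` (FALSE), `raw_fraction`.
#' @examples
#' format_ratio(discrimination_ratio(50, 5))   # "91:9"
#' format_ratio(discrimination_ratio(7.6, 6.1)) # "55:45"
#' @export
discrimination_ratio <- function(re_u, re_c) {
  stopifnot(is.numeric(re_u), is.numeric(re_c),
            length(re_u) == 1L, length(re_c) == 1L)
  if (!is.finite(re_u) || re_u <= 0) {
    stop("re_u must be a positive, detected efficiency", call. = FALSE)
  }
  if (!is.finite(re_c) || re_c < 0) {
    stop("re_c must be finite and >= 0", call. = FALSE)
  }
  new_discrimination_ratio(re_u / (re_u + re_c), is_floor = FALSE)
}

#' Censored floor of the discrimination ratio
#'
#' When the C-ending codon is not reassigned above the limit of detection,
#' the true ratio cannot be computed; substituting the LOD for the censored
#' efficiency gives a lower bound on the U share:
#' \deqn{RE_U / (RE_U + LOD).}
#' Reported with a "greater than or equal to" qualifier (`is_floor = TRUE`).
#'
#' @param re_u Reassignment efficiency of the U-ending codon (percent, > 0).
#' @param lod Limit of detection in percent, default 0.2.
#' @return A `discrimination_ratio` with `is_floor = TRUE`.
#' @examples
#' format_ratio(discrimination_floor(3.6)) # ">=95:5"
#' @export
discrimination_floor <- function(re_u, lod = 0.2) {
  stopifnot(is.numeric(lod), length(lod) == 1L, lod > 0)
  if (!is.numeric(re_u) || length(re_u) != 1L || !is.finite(re_u) ||
      re_u <= 0) {
    stop("re_u must be a positive, detected efficiency", call. = FALSE)
  }
  new_discrimination_ratio(re_u / (re_u + lod), is_floor = TRUE)
}

#' Format a discrimination ratio for display
#'
#' `"55:45"` style; floors carry a `">="` prefix (the ratio is "at least"
#' the stated shares).
#'
#' @param dr A `discrimination_ratio`.
#' @return Character scalar.
#' @export
format_ratio <- function(dr) {
  if (!inherits(dr, "discrimination_ratio")) {
    stop("dr must be a discrimination_ratio", call. = FALSE)
  }
  prefix <- if (isTRUE(dr$is_floor)) "≥" else ""
  sprintf("%s%d:%d", prefix, dr$u_share, dr$c_share)
}

#' @export
print.discrimination_ratio <- function(x, ...) {
  cat(format_ratio(x), "\n")
  invisible(x)
}

#' Minimum inosine-modified fraction detectable as anomalous C3 decoding
#'
#' Inosine at position 34 pairs strongly with C3 while unmodified A34 pairs
#' with C3 only weakly, so a partially modified tRNA population decodes the
#' C-ending codon roughly in proportion to its modified fraction
#' \eqn{f_I}: \eqn{RE_C = f_I \, RE_U} (linear mixing). The modification is
#' detectable as anomalous C-ending reassignment once \eqn{RE_C} clears a
#' detection threshold of \eqn{k} times the assay's limit of detection,
#' giving
#' \deqn{f_{min} = \min(1,\; k \cdot LOD / RE_U).}
#' With the defaults (LOD 0.2%, k = 2) a tRNA reassigning its targeted
#' U-ending codon at 20% reveals as little as 2% modification, while a tRNA
#' at 1% efficiency requires 40% modification.
#'
#' @param re_u Reassignment efficiency of the targeted U-ending codon
#'   (percent, > 0).
#' @param lod Limit of detection in percent (> 0).
#' @param k Detection multiple (>= 1): anomalous decoding is called when
#'   `re_c >= k * lod`.
#' @return Minimum detectable modified fraction in (0, 1\], capped at 1.
#' @examples
#' min_detectable_inosine_fraction(20) # 0.02
#' min_detectable_inosine_fraction(1)  # 0.40
#' @export
min_detectable_inosine_fraction <- function(re_u, lod = 0.2, k = 2) {
  stopifnot(is.numeric(lod), length(lod) == 1L, lod > 0,
            is.numeric(k), length(k) == 1L, k >= 1)
  if (!is.numeric(re_u) || !all(is.finite(re_u)) || any(re_u <= 0)) {
    stop("re_u must be positive", call. = FALSE)
  }
  pmin(1, k * lod / re_u)
}
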