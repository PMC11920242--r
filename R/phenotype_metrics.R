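#' Relative median fluorescence intensity
#'
#' Normalizes a sample's raw MFI to the isotype control, and optionally
#' further to a safe-harbor (AAVS1-targeted) control measured on the same
#' isotype scale: `r = (raw/isotype) / (control/isotype)`.
#'
#' @param raw Raw MFI of the sample (positive).
#' @param isotype Raw MFI of the isotype control (positive).
#' @param control Optional isotype-scale raw MFI of the control cells.
#' @return The relative MFI ratio.
#' @examples
#' relative_mfi(2000, 100)        # 20
#' relative_mfi(3000, 100, 1500)  # 2
#' @export
relative_mfi <- function(raw, isotype, control = NULL) {
  if (any(raw <= 0) || any(isotype <= 0) ||
      (!is.null(control) && any(control <= 0))) {
    stop("MFI values must be positive", call. = FALSE)
  }
  r <- raw / isotype
  if (!is.null(control)) r <- r / (control / isotype)
  r
}

# Shared core of the killing indices: 100 * (1 - odds(A) / odds(B)) with
# odds(x) = x / (100 - x). Zero at A = B, 100 at A = 0 with B > 0; negative
# values indicate enrichment under killing.
killing_index <- function(A, B) {
  if (any(A < 0 | A >= 100) || any(B < 0 | B >= 100)) {
    stop("percentages must lie in [0, 100)", call. = FALSE)
  }
  if (any(B == 0)) {
    stop("reference percentage of 0 leaves the odds ratio undefined",
         call. = FALSE)
  }
  100 * (1 - (A / (100 - A)) / (B / (100 - B)))
}

#' Competitive T-cell killing sensitivity
#'
#' For the tracked (sgRNA-carrying, EGFP+) population:
#' `100 * (1 - odds(A1) / odds(B1))` where `A1` is its percentage after
#' co-culture with T cells, `B1` the paired percentage without T cells,
#' and `odds(x) = x / (100 - x)`.
#'
#' @param A1 Percentage of the tracked population with T cells, in
#'   `[0, 100)`.
#' @param B1 Percentage without T cells, in `(0, 100)`.
#' @return Killing sensitivity in percent (negative when the population is
#'   enriched under killing).
#' @examples
#' killing_sensitivity(25, 50)  # 66.67
#' @export
killing_sensitivity <- function(A1, B1) killing_index(A1, B1)

#' Competitive T-cell killing resistance
#'
#' The same odds-ratio index applied to the wild-type competitor
#' population (`A2`, `B2`).
#'
#' @param A2 Percentage of the competitor population with T cells.
#' @param B2 Percentage without T cells.
#' @return Killing resistance in percent.
#' @examples
#' killing_resistance(75, 50)  # -200
#' @export
killing_resistance <- function(A2, B2) killing_index(A2, B2)

#' Two-sample comparison of replicate measurements
#'
#' Classical two-sample Student's t test (equal-variance by default, Welch
#' optional), with significance stars at the 0.05 / 0.01 / 0.001 / 0.0001
#' levels.
#'
#' @param x,y Numeric replicate values, at least 2 each.
#' @param var_equal Use the pooled-variance t test (default); `FALSE` for
#'   Welch.
#' @return A list: `t`, `df`, `p`, `stars`.
#' @export
compare_groups <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, df = length(x) + length(y) - 2L, p = 1, stars = "n.s."))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = significance_stars(tt$p.value))
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s.")) |> as.character()
}
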