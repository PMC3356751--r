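# Log-singular guard: |ln x| < .log_guard means the log-ratio formulas
# blow up or lose meaning; the measurements must be in mm / mm^2.
.log_guard <- 0.05

.check_log_guard <- function(x, what, unit) {
  bad <- abs(log(x)) < .log_guard
  if (any(bad))
    stop(sprintf(
      paste0("%s = %s is inside the log-singular guard band ",
             "(|ln x| < %.2f); the log-ratio fractal formulas are not ",
             "defined near %s = 1 %s. Check that measurements are in ",
             "mm / mm^2."),
      what, paste(format(x[bad]), collapse = ", "), .log_guard, what, unit))
}

#' Perimeter fractal dimension (log-ratio form)
#'
#' FDP = 2 * ln(P/4) / ln(A), with P in mm and A in mm^2 (natural
#' logarithms). FDP of a smooth outline is about 1 (e.g. a square of
#' side L: P = 4L, A = L^2 gives exactly 1); rougher edges give larger
#' values. The formula is not scale-invariant, so the mm / mm^2 units
#' are part of its definition; inputs with A in the log-singular band
#' around 1 mm^2 are refused.
#'
#' @param P perimeter in mm (> 0); vectorized.
#' @param A area in mm^2 (> 0, outside (exp(-0.05), exp(0.05)));
#'   vectorized.
#' @return FDP values. P = 4 mm (ln(P/4) = 0) returns 0 with a warning.
#' @export
fdp <- function(P, A) {
  if (any(!is.finite(P) | P <= 0) || any(!is.finite(A) | A <= 0))
    stop("fdp: P and A must be finite and > 0")
  .check_log_guard(A, "A", "mm^2")
  if (any(P == 4))
    warning("fdp: P = 4 mm gives ln(P/4) = 0, hence FDP = 0 (degenerate)")
  2 * log(P / 4) / log(A)
}

#' Area fractal dimension (log-ratio form)
#'
#' FDA = ln(A) / ln(ML), with A in mm^2 and ML in mm (natural
#' logarithms). FDA of about 2 means the object fills the plane
#' spanned by its maximum length (A = ML^2 gives exactly 2); smaller
#' values mean an incomplete, irregular plane occupation. Like
#' [fdp()], the formula fixes mm / mm^2 units; ML in the log-singular
#' band around 1 mm is refused.
#'
#' @param A area in mm^2 (> 0); vectorized.
#' @param ML maximum length in mm (> 0, outside
#'   (exp(-0.05), exp(0.05))); vectorized.
#' @return FDA values.
#' @export
fda <- function(A, ML) {
  if (any(!is.finite(A) | A <= 0) || any(!is.finite(ML) | ML <= 0))
    stop("fda: A and ML must be finite and > 0")
  .check_log_guard(ML, "ML", "mm")
  log(A) / log(ML)
}

#' Add per-grain fractal dimensions to a morphometry table
#'
#' In a cohort, individual grains can land inside the log-singular
#' guard bands (A near 1 mm^2 or ML near 1 mm), where [fdp()] / [fda()]
#' are undefined. With `guard = "na"` (default) such grains get `NA`
#' fractal dimensions and a warning lists them, so one borderline grain
#' does not abort a batch; `guard = "error"` propagates the strict
#' per-value errors instead.
#'
#' @param morpho data frame with columns `P_mm`, `A_mm2`, `ML_mm`
#'   (output of [measure_masks()]).
#' @param guard `"na"` or `"error"`, see above.
#' @return The input with `FDP` and `FDA` columns appended.
#' @export
fractal_records <- function(morpho, guard = c("na", "error")) {
  guard <- match.arg(guard)
  stopifnot(all(c("P_mm", "A_mm2", "ML_mm") %in% names(morpho)))
  if (guard == "error") {
    morpho$FDP <- fdp(morpho$P_mm, morpho$A_mm2)
    morpho$FDA <- fda(morpho$A_mm2, morpho$ML_mm)
    return(morpho)
  }
  bad_p <- abs(log(morpho$A_mm2)) < .log_guard
  bad_a <- abs(log(morpho$ML_mm)) < .log_guard
  morpho$FDP <- NA_real_
  morpho$FDA <- NA_real_
  if (any(!bad_p))
    morpho$FDP[!bad_p] <- fdp(morpho$P_mm[!bad_p], morpho$A_mm2[!bad_p])
  if (any(!bad_a))
    morpho$FDA[!bad_a] <- fda(morpho$A_mm2[!bad_a], morpho$ML_mm[!bad_a])
  if (any(bad_p | bad_a)) {
    ids <- if ("source_id" %in% names(morpho))
      morpho$source_id[bad_p | bad_a] else which(bad_p | bad_a)
    warning(sprintf(
      "fractal_records: %d grain(s) inside the log-singular guard band, FDP/FDA set to NA: %s",
      sum(bad_p | bad_a), paste(ids, collapse = ", ")))
  }
  morpho
}

#' Ensemble power-law exponents across a grain population
#'
#' Fits the allometric relations P ~ ML^fdp_slope and A ~ ML^fda_slope
#' across a collection of grains by least squares in log-log space
#' (default) or reduced major axis. For an ensemble of geometrically
#' similar smooth shapes the slopes are 1 and 2; fractional exponents
#' indicate power-law dispersion of the population.
#'
#' @param records data frame with positive columns `ML_mm`, `P_mm`,
#'   `A_mm2`; at least 3 rows.
#' @param method `"ols"` (default) or `"rma"` (reduced major axis).
#' @return List with `fdp_slope`, `fda_slope`, `r2_p`, `r2_a`, `n`.
#' @export
ensemble_exponents <- function(records, method = c("ols", "rma")) {
  method <- match.arg(method)
  stopifnot(all(c("ML_mm", "P_mm", "A_mm2") %in% names(records)))
  n <- nrow(records)
  if (n < 3L) stop("ensemble_exponents: need at least 3 records")
  if (any(records$ML_mm <= 0 | records$P_mm <= 0 | records$A_mm2 <= 0))
    stop("ensemble_exponents: ML, P, A must be > 0")
  lx <- log(records$ML_mm)
  if (stats::var(lx) < .Machine$double.eps * 100)
    stop("ensemble_exponents: degenerate ML variance")
  fit1 <- function(ly) {
    r <- stats::cor(lx, ly)
    slope <- if (method == "ols") {
      stats::cov(lx, ly) / stats::var(lx)
    } else {
      sign(r) * stats::sd(ly) / stats::sd(lx)
    }
    list(slope = slope, r2 = r^2)
  }
  fp <- fit1(log(records$P_mm))
  fa <- fit1(log(records$A_mm2))
  list(fdp_slope = fp$slope, fda_slope = fa$slope,
       r2_p = fp$r2, r2_a = fa$r2, n = n)
}
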