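#' Hypothesis matrix for the condition comparisons
#'
#' Encodes the three planned comparisons over the four condition means, one
#' row per hypothesis (plus the grand-mean intercept row):
#' \describe{
#'   \item{ExpVsControl}{mean(1Hz, 5Hz, 10Hz) - Control: does perceiving a
#'     continuously modified stimulus change band power?}
#'   \item{F5v1}{5Hz - 1Hz}
#'   \item{F10v5}{10Hz - 5Hz}
#' }
#' Every hypothesis row sums to zero; the intercept row holds grand-mean
#' weights (1/4 each), the convention under which the generalized inverse
#' yields an all-ones intercept column in the contrast matrix.
#'
#' @return 4 x 4 numeric matrix, hypotheses x conditions.
#' @export
build_hypothesis_matrix <- function() {
  H <- rbind(Intercept    = c(1, 1, 1, 1) / 4,
             ExpVsControl = c(-1, 1 / 3, 1 / 3, 1 / 3),
             F5v1         = c(0, -1, 1, 0),
             F10v5        = c(0, 0, -1, 1))
  colnames(H) <- .conditions
  H
}

#' Condition contrast matrix via the generalized inverse
#'
#' The non-orthogonal planned comparisons are turned into model contrast
#' columns by applying the Moore-Penrose generalized inverse to the
#' hypothesis matrix, which guarantees each fitted coefficient estimates
#' exactly its hypothesis quantity. Entries are snapped to exact small
#' rationals when the generalized inverse lands within 1e-9 of one.
#'
#' @param H a hypothesis matrix (rows = intercept + hypotheses, columns =
#'   conditions), e.g. from [build_hypothesis_matrix()].
#' @return Conditions x contrasts matrix of class `nf_contrasts`, with the
#'   hypothesis matrix attached as attribute `"hypothesis"`.
#' @export
contrast_from_hypotheses <- function(H) {
  if (qr(H)$rank < nrow(H))
    stop("design error: hypothesis matrix is rank deficient", call. = FALSE)
  X <- MASS::ginv(H)
  snapped <- round(X * 12) / 12
  if (max(abs(snapped - X)) < 1e-9) X <- snapped
  dimnames(X) <- list(colnames(H), rownames(H))
  structure(X, class = c("nf_contrasts", "matrix", "array"),
            hypothesis = H)
}

#' The task's condition contrast matrix
#'
#' Convenience wrapper: generalized inverse of [build_hypothesis_matrix()].
#' Rows are conditions, columns Intercept / ExpVsControl / F5v1 / F10v5,
#' with entries 1, -3/4, 1/4, +-1/3, +-2/3.
#'
#' @return An `nf_contrasts` matrix.
#' @export
condition_contrasts <- function() {
  contrast_from_hypotheses(build_hypothesis_matrix())
}

#' Format a contrast matrix with exact fraction strings
#'
#' @param x an `nf_contrasts` (or plain) matrix.
#' @return Character matrix with entries such as `"-3/4"`.
#' @export
fraction_strings <- function(x) {
  m <- matrix(as.character(MASS::fractions(unclass(x))),
              nrow = nrow(x), dimnames = dimnames(x))
  m
}

#' @export
print.nf_contrasts <- function(x, ...) {
  cat("<nf_contrasts> conditions x contrasts (generalized inverse of the hypothesis matrix)\n")
  print(fraction_strings(x), quote = FALSE)
  invisible(x)
}

#' Serialize contrast and hypothesis matrices
#'
#' Writes both matrices to a JSON file with exact fraction strings, or to a
#' pair of CSVs.
#'
#' @param contrasts an `nf_contrasts`.
#' @param path output path; `.json` gets a single JSON document, anything
#'   else a pair of CSVs (`*_contrasts.csv`, `*_hypotheses.csv`).
#' @return Invisibly, `path`.
#' @export
write_contrasts <- function(contrasts, path) {
  H <- attr(contrasts, "hypothesis")
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(contrasts = as.data.frame(fraction_strings(contrasts)),
           hypotheses = as.data.frame(fraction_strings(H))),
      path, auto_unbox = TRUE)
  } else {
    utils::write.csv(fraction_strings(contrasts),
                     paste0(path, "_contrasts.csv"))
    utils::write.csv(fraction_strings(H), paste0(path, "_hypotheses.csv"))
  }
  invisible(path)
}

#' Contrast- and trial-code a band-power table for modelling
#'
#' Adds the model's fixed-effect columns to a (z-scored) band-power table:
#' \describe{
#'   \item{condition}{within-condition trial covariate `trial_c`
#'     (trial - 1, so condition effects are evaluated at the first trial of
#'     each condition), the three contrast-coded condition columns, and the
#'     trial x contrast interactions.}
#'   \item{whole_task}{`trial_c` = global trial - 1 (0..31), no condition
#'     columns: the exploratory whole-session trend model.}
#'   \item{control_only}{Control rows only, `trial_c` = trial - 1: the
#'     per-condition trial-repetition model.}
#' }
#'
#' @param records a band-power table (usually after [zscore_powers()]).
#' @param contrasts an `nf_contrasts`, default [condition_contrasts()].
#' @param analysis which design variant to encode.
#' @return The table with design columns added; the fixed-term names (model
#'   columns beyond the intercept) are attached as attribute
#'   `"fixed_terms"`, and the variant as `"analysis"`.
#' @export
encode_design <- function(records, contrasts = condition_contrasts(),
                          analysis = c("condition", "whole_task",
                                       "control_only")) {
  analysis <- match.arg(analysis)
  needed <- c("subject", "condition", "trial_index", "global_trial_index")
  stopifnot(all(needed %in% names(records)))
  unknown <- setdiff(unique(records$condition), rownames(contrasts))
  if (length(unknown))
    stop("design error: unknown condition label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  if (analysis == "whole_task") {
    records$trial_c <- records$global_trial_index - 1
    fixed <- "trial_c"
  } else if (analysis == "control_only") {
    records <- records[records$condition == "Control", , drop = FALSE]
    records$trial_c <- records$trial_index - 1
    fixed <- "trial_c"
  } else {
    records$trial_c <- records$trial_index - 1
    idx <- match(records$condition, rownames(contrasts))
    cond_cols <- setdiff(colnames(contrasts), "Intercept")
    for (cc in cond_cols) records[[cc]] <- contrasts[idx, cc]
    for (cc in cond_cols)
      records[[paste0("trial_x_", cc)]] <- records$trial_c * records[[cc]]
    fixed <- c("trial_c", cond_cols, paste0("trial_x_", cond_cols))
  }
  attr(records, "fixed_terms") <- fixed
  attr(records, "analysis") <- analysis
  records
}
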