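#' Composite EAU clinical score
#'
#' The overall retinal inflammation grade of one eye in experimental
#' autoimmune uveoretinitis (EAU): the arithmetic mean of the optic disc,
#' retinal vessel and retinal tissue grades, unrounded. Grades are
#' nonnegative numbers up to `max_grade` (default 4, the usual C57BL/6
#' scale); half-point or finer increments are accepted.
#'
#' @param optic_disc,retinal_vessels,retinal_tissue Component grades;
#'   vectorized (recycled to a common length).
#' @param max_grade Upper bound of the grading scale.
#' @return Numeric vector of composite scores, bounded by the component
#'   minimum and maximum.
#' @examples
#' eau_composite(1, 2, 3)   # 2
#' @export
eau_composite <- function(optic_disc, retinal_vessels, retinal_tissue,
                          max_grade = 4) {
  comp <- list(optic_disc = optic_disc, retinal_vessels = retinal_vessels,
               retinal_tissue = retinal_tissue)
  for (nm in names(comp)) {
    x <- comp[[nm]]
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > max_grade))
      stop(sprintf("%s: grades must be numbers in [0, %g]", nm, max_grade),
           call. = FALSE)
  }
  (optic_disc + retinal_vessels + retinal_tissue) / 3
}

#' Append composite EAU scores to a grade table
#'
#' Reads a CSV with columns `animal_id`, `eye`, `optic_disc`,
#' `retinal_vessels`, `retinal_tissue`, appends a `composite` column, and
#' optionally writes the result back out.
#'
#' @param input Path to the input CSV, or a data frame with the columns
#'   above.
#' @param output Optional path for the augmented CSV.
#' @param max_grade Upper bound of the grading scale.
#' @return The augmented data frame (invisibly when `output` is given).
#' @export
score_eau_table <- function(input, output = NULL, max_grade = 4) {
  df <- if (is.data.frame(input)) input else utils::read.csv(input)
  need <- c("optic_disc", "retinal_vessels", "retinal_tissue")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$composite <- eau_composite(df$optic_disc, df$retinal_vessels,
                                df$retinal_tissue, max_grade = max_grade)
  if (!is.null(output)) {
    utils::write.csv(df, output, row.names = FALSE)
    return(invisible(df))
  }
  df
}
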