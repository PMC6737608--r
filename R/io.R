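# CSV interfaces: subject-level case-control data and the standard
# summary-table schema
#   factor, kind, prevalence, beta_ave, or_ave, approx_paf, exact_paf,
#   ci_lower, ci_upper
# with prevalence and PAF columns stored as proportions.

summary_schema <- c("factor", "kind", "prevalence", "beta_ave", "or_ave",
                    "approx_paf", "exact_paf", "ci_lower", "ci_upper")

#' Read subject-level case-control data from CSV
#'
#' Requires a header row; checks that the declared outcome, exposure
#' and confounder columns exist.  Rows with missing values in declared
#' columns are dropped (with a message) when the data are fitted.
#'
#' @param path CSV file.
#' @param outcome,exposures,confounders Column names to validate
#'   (exposures may name several columns).
#' @return A data frame.
#' @export
read_case_control <- function(path, outcome = "y", exposures = character(),
                              confounders = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("no rows in ", path)
  need <- c(outcome, exposures, confounders)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  d
}

#' Read a risk-factor summary table from CSV
#'
#' The table has one row per risk factor in the standard schema (see
#' [write_summary_table()]); `factor`, `prevalence` and `beta_ave` are
#' required, the remaining columns optional.  Prevalences and PAFs are
#' proportions, `beta_ave` a natural-log odds ratio.
#'
#' @param path CSV file.
#' @param require Columns that must be present.
#' @return A data frame.
#' @export
read_summary_table <- function(path,
                               require = c("factor", "prevalence",
                                           "beta_ave")) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("no rows in ", path)
  miss <- setdiff(require, names(d))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  d
}

#' Write a risk-factor summary table as CSV
#'
#' @param tab A data frame (e.g. from [paf_table()]); columns are
#'   reordered into the standard schema, missing ones filled with
#'   `NA`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  for (col in summary_schema)
    if (!col %in% names(tab)) tab[[col]] <- NA
  extra <- setdiff(names(tab), summary_schema)
  utils::write.csv(tab[c(summary_schema, extra)], path, row.names = FALSE)
  invisible(path)
}

#' Bundled risk-factor summary table
#'
#' Path to the packaged summary table of the ten major stroke risk
#' factors from the INTERSTROKE case-control study (published
#' summary rows: average log-odds ratio, control prevalence, and the
#' published approximate/exact PAF with 99% bootstrap intervals).
#' PAF and prevalence columns are proportions.
#'
#' @return File path of the CSV.
#' @export
#' @examples
#' head(read_summary_table(interstroke_summary_path()))
interstroke_summary_path <- function() {
  system.file("extdata", "interstroke_summary.csv", package = "paftools",
              mustWork = TRUE)
}
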