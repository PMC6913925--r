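#' Contamination profiles calibrating the synthetic generator
#'
#' Per-(sample type, stratum) means and standard deviations of log10
#' concentration in matrix reporting units, shipped as a plain-text table in
#' `inst/extdata/`. `"overall"` rows pool all neighborhoods (their SD mixes
#' between- and within-neighborhood variability and is the right choice for
#' single-stratum simulations); `"category"` rows give the low-income,
#' high-income and floating neighborhood strata; `"corporation"` rows carry
#' the municipal drinking-water means for the two city corporations (no SD
#' is available for these, so they calibrate contrasts, not simulations).
#'
#' @param stratum_type Optional filter: `"overall"`, `"category"` or
#'   `"corporation"`.
#' @return A tibble with columns `sample_type`, `stratum_type`, `stratum`,
#'   `mu`, `sigma`, `n`.
#' @examples
#' contamination_profiles("overall")
#' @export
contamination_profiles <- function(stratum_type = NULL) {
  path <- system.file("extdata", "contamination_profiles.csv",
                      package = "mpnenv", mustWork = TRUE)
  prof <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (!is.null(stratum_type)) {
    keep <- match.arg(stratum_type,
                      c("overall", "category", "corporation"))
    prof <- prof[prof$stratum_type == keep, , drop = FALSE]
  }
  prof
}

#' Default multi-neighborhood study design
#'
#' The sampling frame the generator emulates: ten neighborhoods (four
#' low-income, four high-income, two floating/transient), five in each city
#' corporation (DNCC north, DSCC south), crossed with the ten sample types
#' at a fixed number of samples per (neighborhood x type) cell. The default
#' yields 10 x 10 x 10 = 1000 samples.
#'
#' @param samples_per_cell Samples per neighborhood x sample-type cell.
#' @param sample_types Character vector of sample types to include.
#' @return A list of class `study_design` with `neighborhoods` (tibble:
#'   `neighborhood`, `category`, `corporation`), `sample_types`,
#'   `samples_per_cell` and the per-type dilution `schemes`.
#' @export
study_design <- function(samples_per_cell = 10,
                         sample_types = mpnenv::sample_types()$sample_type) {
  if (samples_per_cell < 1) {
    stop("`samples_per_cell` must be at least 1", call. = FALSE)
  }
  unknown <- setdiff(sample_types, mpnenv::sample_types()$sample_type)
  if (length(unknown) > 0) {
    stop("unknown sample types: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  neighborhoods <- tibble::tibble(
    neighborhood = c("Gabtoli", "Kamalapur", "Kalshi", "Shampur", "Badda",
                     "Hazaribagh", "Uttarkhan", "Motijheel", "Gulshan",
                     "Dhanmondi"),
    category = c("floating", "floating", "low_income", "low_income",
                 "low_income", "low_income", "high_income", "high_income",
                 "high_income", "high_income"),
    corporation = c("DNCC", "DSCC", "DNCC", "DSCC", "DNCC",
                    "DSCC", "DNCC", "DSCC", "DNCC", "DSCC")
  )
  structure(
    list(neighborhoods = neighborhoods, sample_types = sample_types,
         samples_per_cell = as.integer(samples_per_cell),
         schemes = dilution_schemes()),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d neighborhoods x %d sample types x %d samples = %d\n",
    nrow(x$neighborhoods), length(x$sample_types), x$samples_per_cell,
    nrow(x$neighborhoods) * length(x$sample_types) * x$samples_per_cell
  ))
  invisible(x)
}
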