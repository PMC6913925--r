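#' Sample-type vocabulary
#'
#' The ten environmental compartments of the sampling design, with the
#' reporting unit each is expressed in. Water types (drains included) are
#' reported per 100 mL, latrine swabs per swab, produce per single serving,
#' street food and soil per gram.
#'
#' @return A tibble with columns `sample_type` and `unit`.
#' @export
sample_types <- function() {
  tibble::tibble(
    sample_type = c("latrine_swab", "soil", "drain_water", "bathing_water",
                    "municipal_water", "non_municipal_water", "surface_water",
                    "produce", "street_food", "floodwater"),
    unit = c("per_swab", "per_gram", "per_100mL", "per_100mL", "per_100mL",
             "per_100mL", "per_100mL", "per_serving", "per_gram", "per_100mL")
  )
}

water_types <- function() {
  c("drain_water", "bathing_water", "municipal_water", "non_municipal_water",
    "surface_water", "floodwater")
}

neighborhood_categories <- function() c("low_income", "high_income", "floating")

city_corporations <- function() c("DNCC", "DSCC")

#' Matrix processing metadata
#'
#' Laboratory processing volumes and masses that convert a concentration in
#' the assayed fluid into the matrix reporting unit. Defaults follow the
#' field protocol: a 10 g street-food aliquot homogenized in 90 mL distilled
#' water, a 10 g soil aliquot eluted in 20 mL PBST, latrine swabs eluted in
#' 14 mL PBST, and whole produce rinsed in 500 mL PBST.
#'
#' @param soil_mass Soil aliquot, g.
#' @param soil_eluate_volume PBST added to the soil aliquot, mL.
#' @param soil_water_fraction Fraction of the soil mass contributing water to
#'   the eluate (0 = dry-mass accounting; no moisture data are collected by
#'   default).
#' @param swab_eluate_volume PBST volume the swab is eluted into, mL.
#' @param food_mass Street-food aliquot, g.
#' @param food_diluent_volume Distilled water used to homogenize the food
#'   aliquot, mL.
#' @param produce_rinse_volume PBST rinse volume for a produce sample, mL.
#' @param produce_weight Recorded weight of the rinsed produce, g (reporting
#'   metadata only; the serving unit is the whole rinsed sample).
#' @return An object of class `matrix_metadata`.
#' @export
matrix_metadata <- function(soil_mass = 10, soil_eluate_volume = 20,
                            soil_water_fraction = 0,
                            swab_eluate_volume = 14,
                            food_mass = 10, food_diluent_volume = 90,
                            produce_rinse_volume = 500,
                            produce_weight = NA_real_) {
  vols <- c(soil_mass = soil_mass, soil_eluate_volume = soil_eluate_volume,
            swab_eluate_volume = swab_eluate_volume, food_mass = food_mass,
            food_diluent_volume = food_diluent_volume,
            produce_rinse_volume = produce_rinse_volume)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    stop("all matrix masses and volumes must be positive", call. = FALSE)
  }
  if (soil_water_fraction < 0 || soil_water_fraction > 1) {
    stop("`soil_water_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(soil_mass = soil_mass, soil_eluate_volume = soil_eluate_volume,
         soil_water_fraction = soil_water_fraction,
         swab_eluate_volume = swab_eluate_volume,
         food_mass = food_mass, food_diluent_volume = food_diluent_volume,
         produce_rinse_volume = produce_rinse_volume,
         produce_weight = produce_weight),
    class = "matrix_metadata"
  )
}

#' Substitute censored tray estimates
#'
#' Applies the study's detection-limit substitution: a tray with no positive
#' wells contributes 0.5 MPN (half the lower quantifiable bound of 1 MPN per
#' tray) and an all-positive tray contributes 2419.6 MPN (the upper bound of
#' the quantifiable range); a quantifiable tray contributes its MLE
#' unchanged. Values are per tray, before dilution scaling.
#'
#' @param est A `tray_estimate` from [mpn_estimate()].
#' @param lower_sub,upper_sub Substitution constants for nondetect and
#'   overrange trays.
#' @return A single MPN value per reference volume.
#' @examples
#' substitute_censored(mpn_estimate(0, 0))    # 0.5
#' substitute_censored(mpn_estimate(49, 48))  # 2419.6
#' @export
substitute_censored <- function(est, lower_sub = 0.5, upper_sub = 2419.6) {
  stopifnot(inherits(est, "tray_estimate"))
  switch(est$status,
    nondetect = lower_sub,
    overrange = upper_sub,
    quantifiable = est$mpn,
    stop("unknown tray estimate status: ", est$status, call. = FALSE)
  )
}

#' Combine a serial-dilution series into one assay-fluid concentration
#'
#' Implements the censoring-aware aggregation rules used for multi-dilution
#' samples. Each tray estimate is scaled by its dilution factor to the
#' concentration in undiluted assay fluid; then:
#'
#' * all trays nondetect: the lowest dilution (the most sensitive tray) is
#'   used with the 0.5 MPN substitution — the result `0.5 * min(D)` is
#'   left-censored;
#' * all trays overrange: the highest dilution is used with the 2419.6 MPN
#'   substitution — the result `2419.6 * max(D)` is right-censored;
#' * otherwise the arithmetic mean of `mpn * D` over the quantifiable trays,
#'   ignoring censored trays, reported as `interval_ok`.
#'
#' The rules apply verbatim to however many dilutions were assayed (1-3 in
#' the default schemes). A logically inconsistent pattern — a quantifiable
#' tray together with a nondetect at a *lower* dilution — still follows the
#' third rule and is flagged.
#'
#' @param dilution_factor Numeric vector of fold-dilutions (>= 1), one per
#'   tray.
#' @param estimates List of `tray_estimate` objects, parallel to
#'   `dilution_factor`.
#' @param lower_sub,upper_sub Censoring substitution constants, per tray.
#' @param average Averaging scale across quantifiable trays: the protocol's
#'   `"arithmetic"` mean of MPN values (default), or `"geometric"`.
#' @return A list with `value` (MPN per reference volume of undiluted assay
#'   fluid), `censoring` (`"left"`, `"interval_ok"`, `"right"`),
#'   `n_trays_used`, and `inconsistent` (logical flag).
#' @examples
#' ests <- list(mpn_estimate(30, 10), mpn_estimate(4, 1))
#' combine_dilutions(c(100, 1000), ests)
#' @export
combine_dilutions <- function(dilution_factor, estimates,
                              lower_sub = 0.5, upper_sub = 2419.6,
                              average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  avg <- if (average == "arithmetic") mean else function(x) exp(mean(log(x)))
  if (length(estimates) == 0) {
    stop("at least one tray is required", call. = FALSE)
  }
  if (length(dilution_factor) != length(estimates)) {
    stop("`dilution_factor` and `estimates` must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(dilution_factor)) || any(dilution_factor < 1)) {
    stop("dilution factors must be finite and >= 1", call. = FALSE)
  }
  if (anyDuplicated(dilution_factor)) {
    stop("dilution factors within a sample must be distinct", call. = FALSE)
  }
  status <- vapply(estimates, function(e) e$status, character(1))

  if (all(status == "nondetect")) {
    return(list(value = lower_sub * min(dilution_factor), censoring = "left",
                n_trays_used = 1L, inconsistent = FALSE))
  }
  if (all(status == "overrange")) {
    return(list(value = upper_sub * max(dilution_factor), censoring = "right",
                n_trays_used = 1L, inconsistent = FALSE))
  }
  ok <- status == "quantifiable"
  if (!any(ok)) {
    # mixed nondetect + overrange with no quantifiable tray: no dilution
    # agreed; fall back to the midpoint rule is not defined by the protocol,
    # so average the two substituted extremes scaled by their dilutions
    vals <- vapply(seq_along(estimates), function(i) {
      substitute_censored(estimates[[i]], lower_sub, upper_sub) *
        dilution_factor[i]
    }, numeric(1))
    return(list(value = avg(vals), censoring = "interval_ok",
                n_trays_used = length(vals), inconsistent = TRUE))
  }
  scaled <- vapply(which(ok), function(i) {
    estimates[[i]]$mpn * dilution_factor[i]
  }, numeric(1))
  # nondetect at a lower dilution than a quantifiable tray cannot happen
  # under the dilution model; flag it but keep rule (c)
  inconsistent <- any(vapply(seq_along(estimates), function(i) {
    status[i] == "nondetect" &&
      any(dilution_factor[ok] > dilution_factor[i])
  }, logical(1)))
  list(value = avg(scaled), censoring = "interval_ok",
       n_trays_used = sum(ok), inconsistent = inconsistent)
}

#' Normalize an assay-fluid concentration to matrix reporting units
#'
#' Converts an MPN per 100 mL of undiluted assay fluid into the reporting
#' unit of the sample matrix, using the laboratory processing volumes in
#' [matrix_metadata()]:
#'
#' * water types: identity (MPN/100 mL);
#' * latrine swab: total MPN recovered in the eluate, i.e.
#'   `conc * swab_eluate_volume / 100` per swab;
#' * produce: total MPN in the rinse, `conc * produce_rinse_volume / 100`
#'   per serving (the rinsed sample is one serving);
#' * street food: the homogenate volume is `food_mass + food_diluent_volume`
#'   (the aliquot contributes its own volume), so per gram
#'   `conc * ((food_mass + food_diluent_volume) / 100) / food_mass`;
#' * soil: eluate volume is `soil_mass * soil_water_fraction +
#'   soil_eluate_volume` (dry soil contributes no volume by default), per
#'   gram analogously.
#'
#' @param assay_conc MPN per 100 mL of undiluted assay fluid; must be
#'   positive.
#' @param sample_type One of [sample_types()]`$sample_type`.
#' @param matrix A [matrix_metadata()].
#' @return A list with `value`, `log10_value` (negative values permitted —
#'   e.g. sub-MPN-per-swab loads), and `unit`.
#' @examples
#' normalize_units(5, "latrine_swab")  # 0.7 MPN/swab
#' @export
normalize_units <- function(assay_conc, sample_type,
                            matrix = matrix_metadata()) {
  if (length(assay_conc) != 1 || !is.finite(assay_conc) || assay_conc <= 0) {
    stop("`assay_conc` must be a single positive value", call. = FALSE)
  }
  types <- sample_types()
  if (!sample_type %in% types$sample_type) {
    stop(sprintf("unknown sample type '%s'", sample_type), call. = FALSE)
  }
  unit <- types$unit[types$sample_type == sample_type]
  value <- if (sample_type %in% water_types()) {
    assay_conc
  } else if (sample_type == "latrine_swab") {
    assay_conc * matrix$swab_eluate_volume / 100
  } else if (sample_type == "produce") {
    assay_conc * matrix$produce_rinse_volume / 100
  } else if (sample_type == "street_food") {
    homogenate <- matrix$food_mass + matrix$food_diluent_volume
    assay_conc * (homogenate / 100) / matrix$food_mass
  } else { # soil
    eluate <- matrix$soil_mass * matrix$soil_water_fraction +
      matrix$soil_eluate_volume
    assay_conc * (eluate / 100) / matrix$soil_mass
  }
  list(value = value, log10_value = log10(value), unit = unit)
}

# Inverse of normalize_units: reporting-unit concentration -> assay fluid
# MPN per 100 mL. Used by the synthetic generator.
reporting_to_assay <- function(value, sample_type,
                               matrix = matrix_metadata()) {
  factor <- normalize_units(1, sample_type, matrix)$value
  value / factor
}

#' Process one sample's dilution series to a concentration result
#'
#' Composes tray-level MPN estimation, censoring substitution, dilution
#' aggregation and unit normalization for a single environmental sample.
#'
#' @param sample_type One of [sample_types()]`$sample_type`.
#' @param dilution_factor Fold-dilution per tray (>= 1, distinct).
#' @param p_large,p_small Positive well counts per tray, parallel vectors.
#' @param geometry A [tray_geometry()].
#' @param matrix A [matrix_metadata()].
#' @param lower_sub,upper_sub Censoring substitution constants.
#' @return A one-row tibble: `value`, `log10_value`, `unit`, `censoring`,
#'   `n_trays_used`, `inconsistent`.
#' @examples
#' process_sample("drain_water", c(1e5, 1e6), p_large = c(49, 10),
#'                p_small = c(48, 2))
#' @export
process_sample <- function(sample_type, dilution_factor, p_large, p_small,
                           geometry = tray_geometry(),
                           matrix = matrix_metadata(),
                           lower_sub = 0.5, upper_sub = 2419.6,
                           average = c("arithmetic", "geometric")) {
  stopifnot(length(dilution_factor) == length(p_large),
            length(p_large) == length(p_small))
  ests <- lapply(seq_along(dilution_factor), function(i) {
    mpn_estimate(p_large[i], p_small[i], geometry)
  })
  agg <- combine_dilutions(dilution_factor, ests, lower_sub, upper_sub,
                           average = average)
  norm <- normalize_units(agg$value, sample_type, matrix)
  tibble::tibble(
    value = norm$value, log10_value = norm$log10_value, unit = norm$unit,
    censoring = agg$censoring, n_trays_used = agg$n_trays_used,
    inconsistent = agg$inconsistent
  )
}

#' Process a long-format table of tray observations
#'
#' The workhorse for study datasets: takes tray-level rows (one row per tray,
#' i.e. per sample x dilution) and returns one concentration per sample in
#' its matrix reporting unit. Input columns `sample_id`, `sample_type`,
#' `dilution_factor`, `p_large`, `p_small` are required; `neighborhood`,
#' `category` and `corporation` are carried through when present.
#'
#' @param trays Data frame of tray observations (long format).
#' @param config A [run_config()] carrying geometry, matrix volumes and
#'   substitution constants.
#' @return A tibble with one row per sample: metadata columns plus `value`,
#'   `log10_value`, `unit`, `censoring`, `n_trays_used`, `inconsistent`.
#' @export
process_samples <- function(trays, config = run_config()) {
  required <- c("sample_id", "sample_type", "dilution_factor",
                "p_large", "p_small")
  missing_cols <- setdiff(required, names(trays))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(trays[c("sample_id", "dilution_factor")])) {
    stop("duplicate (sample_id, dilution_factor) rows", call. = FALSE)
  }
  carry <- intersect(c("sample_type", "neighborhood", "category",
                       "corporation"), names(trays))
  trays |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", carry)))) |>
    dplyr::group_modify(function(df, key) {
      process_sample(
        key$sample_type, df$dilution_factor, df$p_large, df$p_small,
        geometry = config$geometry, matrix = config$matrix,
        lower_sub = config$lower_sub, upper_sub = config$upper_sub,
        average = config$average
      )
    }) |>
    dplyr::ungroup()
}
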