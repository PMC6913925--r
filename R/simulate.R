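#' Simulate one environmental sample's dilution series
#'
#' Generates tray well counts under the same Poisson-dilution model the MPN
#' estimator inverts. A true log10 concentration is drawn from
#' Normal(`mu`, `sigma`) on the matrix reporting scale, converted back to an
#' assay-fluid concentration by inverting the unit normalization, and each
#' well of each tray turns positive independently with probability
#' `1 - exp(-(lambda / D) * v_well)` where `lambda` is the per-mL
#' concentration of the assay fluid and `D` the tray's dilution factor.
#' True values far below the scheme's quantifiable band therefore yield
#' honest all-negative trays, and values above it all-positive trays.
#'
#' @param sample_type One of [sample_types()]`$sample_type`.
#' @param mu,sigma Mean and SD of the true log10 concentration in reporting
#'   units.
#' @param scheme Dilution factors for this sample's trays; defaults to the
#'   type's entry in [dilution_schemes()].
#' @param geometry A [tray_geometry()].
#' @param matrix A [matrix_metadata()].
#' @param seed Integer seed; the record is fully reproducible from it.
#' @return A tibble with one row per tray: `sample_type`,
#'   `dilution_factor`, `p_large`, `p_small`, `true_log10`.
#' @examples
#' simulate_sample("drain_water", mu = 6.91, sigma = 0.92, seed = 7)
#' @export
simulate_sample <- function(sample_type, mu, sigma,
                            scheme = dilution_schemes()[[sample_type]],
                            geometry = tray_geometry(),
                            matrix = matrix_metadata(),
                            seed = 1L) {
  stopifnot(length(mu) == 1, length(sigma) == 1, sigma >= 0)
  if (is.null(scheme)) {
    stop(sprintf("no dilution scheme for sample type '%s'", sample_type),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  true_log10 <- stats::rnorm(1, mu, sigma)
  assay_conc <- reporting_to_assay(10^true_log10, sample_type, matrix)
  lambda <- assay_conc / geometry$reference_volume  # per mL of assay fluid
  draw <- function(D) {
    pr_l <- -expm1(-(lambda / D) * geometry$v_large)
    pr_s <- if (geometry$n_small > 0) {
      -expm1(-(lambda / D) * geometry$v_small)
    } else 0
    c(stats::rbinom(1, geometry$n_large, pr_l),
      stats::rbinom(1, geometry$n_small, pr_s))
  }
  counts <- vapply(scheme, draw, numeric(2))
  tibble::tibble(
    sample_type = sample_type,
    dilution_factor = as.numeric(scheme),
    p_large = as.integer(counts[1, ]),
    p_small = as.integer(counts[2, ]),
    true_log10 = true_log10
  )
}

#' Simulate a cohort of samples of one type
#'
#' Convenience wrapper drawing `n` independent samples from one
#' contamination profile; per-sample seeds are derived from `seed` (see
#' [simulate_study()]).
#'
#' @inheritParams simulate_sample
#' @param n Number of samples.
#' @param id_prefix Prefix for generated `sample_id`s.
#' @return A long-format tibble of tray observations, one row per tray.
#' @examples
#' simulate_stratum(5, "street_food", mu = 1.79, sigma = 1.18, seed = 11)
#' @export
simulate_stratum <- function(n, sample_type, mu, sigma,
                             scheme = dilution_schemes()[[sample_type]],
                             geometry = tray_geometry(),
                             matrix = matrix_metadata(),
                             seed = 1L, id_prefix = sample_type) {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, n)
  recs <- lapply(seq_len(n), function(i) {
    rec <- simulate_sample(sample_type, mu, sigma, scheme, geometry, matrix,
                           seed = seeds[i])
    rec$sample_id <- sprintf("%s_%04d", id_prefix, i)
    rec
  })
  dplyr::bind_rows(recs) |>
    dplyr::relocate("sample_id")
}

# One substream seed per sample, drawn under the study seed so that any
# subset of samples can be regenerated without simulating the whole study.
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a full multi-neighborhood study
#'
#' Crosses the design's neighborhoods and sample types, looks up the
#' contamination profile of each cell, and emits tray observations in the
#' long input schema of [process_samples()]. Profiles are matched by the
#' neighborhood's stratum when `stratum_type = "category"` (the default,
#' reproducing between-category differences) or by the pooled profile when
#' `"overall"`.
#'
#' @param design A [study_design()].
#' @param profiles A profile table as from [contamination_profiles()].
#' @param stratum_type `"category"` or `"overall"`.
#' @param geometry,matrix Assay configuration shared by all samples.
#' @param seed Study seed; per-sample seeds are derived from it.
#' @return A long-format tibble: `sample_id`, `sample_type`, `neighborhood`,
#'   `category`, `corporation`, `dilution_factor`, `p_large`, `p_small`,
#'   `true_log10`.
#' @examples
#' design <- study_design(samples_per_cell = 1)
#' sim <- simulate_study(design, seed = 42)
#' @export
simulate_study <- function(design = study_design(),
                           profiles = contamination_profiles(),
                           stratum_type = c("category", "overall"),
                           geometry = tray_geometry(),
                           matrix = matrix_metadata(),
                           seed = 1L) {
  stratum_type <- match.arg(stratum_type)
  stopifnot(inherits(design, "study_design"))
  profiles <- profiles[profiles$stratum_type == stratum_type, , drop = FALSE]

  cells <- tidyr::expand_grid(
    design$neighborhoods,
    sample_type = design$sample_types
  )
  cells$stratum <- if (stratum_type == "category") cells$category else "overall"
  cells <- dplyr::left_join(
    cells, profiles[c("sample_type", "stratum", "mu", "sigma")],
    by = c("sample_type", "stratum")
  )
  bad <- is.na(cells$mu) | is.na(cells$sigma)
  if (any(bad)) {
    stop("no contamination profile for cell(s): ",
         paste(unique(sprintf("%s/%s", cells$sample_type[bad],
                              cells$stratum[bad])), collapse = ", "),
         call. = FALSE)
  }

  n_cells <- nrow(cells)
  per <- design$samples_per_cell
  seeds <- derive_seeds(seed, n_cells * per)
  out <- vector("list", n_cells * per)
  k <- 0L
  for (ci in seq_len(n_cells)) {
    cell <- cells[ci, ]
    for (j in seq_len(per)) {
      k <- k + 1L
      rec <- simulate_sample(
        cell$sample_type, cell$mu, cell$sigma,
        scheme = design$schemes[[cell$sample_type]],
        geometry = geometry, matrix = matrix, seed = seeds[k]
      )
      rec$sample_id <- sprintf("%s_%s_%03d", cell$neighborhood,
                               cell$sample_type, j)
      rec$neighborhood <- cell$neighborhood
      rec$category <- cell$category
      rec$corporation <- cell$corporation
      out[[k]] <- rec
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("sample_id", "sample_type", "neighborhood", "category",
                    "corporation")
}
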