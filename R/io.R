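#' Read tray-level sample records
#'
#' Reads a long-format table of tray observations (one row per sample x
#' dilution) and validates it against the study vocabulary and the tray
#' geometry. CSV is the native format; a Stata `.dta` export of a study
#' dataset can be ingested by supplying `column_map`, a named character
#' vector mapping the required schema names to the file's column names
#' (Stata files are read with `foreign::read.dta`, which supports formats up
#' to Stata 12 — re-save or export newer files first).
#'
#' @param path File path (`.csv` or `.dta`).
#' @param geometry A [tray_geometry()]; well counts are validated against
#'   its bounds.
#' @param column_map Optional named character vector, e.g.
#'   `c(sample_id = "sampleid", p_large = "lgwells", ...)`.
#' @return A validated tibble with columns `sample_id`, `sample_type`,
#'   `dilution_factor`, `p_large`, `p_small` and any metadata columns
#'   present (`neighborhood`, `category`, `corporation`, ...).
#' @export
read_sample_records <- function(path, geometry = tray_geometry(),
                                column_map = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- if (grepl("\\.dta$", path, ignore.case = TRUE)) {
    if (!requireNamespace("foreign", quietly = TRUE)) {
      stop("reading .dta files requires the 'foreign' package", call. = FALSE)
    }
    tibble::as_tibble(foreign::read.dta(path))
  } else {
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  }
  if (!is.null(column_map)) {
    found <- column_map[column_map %in% names(df)]
    missing_src <- setdiff(column_map, names(df))
    if (length(missing_src) > 0) {
      stop("column_map names absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    names(df)[match(found, names(df))] <- names(column_map)[
      match(found, column_map)]
  }
  validate_sample_records(df, geometry)
}

#' Validate a tray-observation table
#'
#' @param df Data frame in the long input schema.
#' @param geometry A [tray_geometry()].
#' @return The validated tibble (invisibly the same data).
#' @export
validate_sample_records <- function(df, geometry = tray_geometry()) {
  required <- c("sample_id", "sample_type", "dilution_factor",
                "p_large", "p_small")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  line <- seq_len(nrow(df))
  fail <- function(bad, what) {
    if (any(bad)) {
      stop(sprintf("%s (rows: %s)", what,
                   paste(utils::head(line[bad], 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  fail(!df$sample_type %in% sample_types()$sample_type,
       "unknown sample_type")
  fail(!is.finite(df$dilution_factor) | df$dilution_factor < 1,
       "dilution_factor must be >= 1")
  fail(!is.finite(df$p_large) | df$p_large < 0 |
         df$p_large > geometry$n_large | df$p_large != round(df$p_large),
       sprintf("p_large must be a whole number in [0, %d]",
               geometry$n_large))
  fail(!is.finite(df$p_small) | df$p_small < 0 |
         df$p_small > geometry$n_small | df$p_small != round(df$p_small),
       sprintf("p_small must be a whole number in [0, %d]",
               geometry$n_small))
  if (anyDuplicated(df[c("sample_id", "dilution_factor")])) {
    dup <- duplicated(df[c("sample_id", "dilution_factor")])
    fail(dup, "duplicate (sample_id, dilution_factor)")
  }
  if ("category" %in% names(df)) {
    fail(!is.na(df$category) &
           !df$category %in% neighborhood_categories(),
         "category outside the study design vocabulary")
  }
  if ("corporation" %in% names(df)) {
    fail(!is.na(df$corporation) &
           !df$corporation %in% city_corporations(),
         "corporation outside the study design vocabulary")
  }
  tibble::as_tibble(df)
}

#' Write an output table with a provenance header
#'
#' Writes CSV preceded by `#`-comment lines recording the configuration
#' hash and seed, so every artifact can be traced to the run that produced
#' it. Files written this way are re-readable with
#' [read_sample_records()] / `readr::read_csv(comment = "#")`.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param config A [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(x, path, config = run_config()) {
  header <- c(
    sprintf("# mpnenv output; config_hash=%s; seed=%d",
            config_hash(config), config$seed),
    sprintf("# substitutions: lower=%g upper=%g; averaging=%s",
            config$lower_sub, config$upper_sub, config$average)
  )
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Replicate the study-style summary tables from a tray-level dataset
#'
#' Runs the full pipeline on a long-format tray dataset and produces the
#' standard reporting set: per-neighborhood means/SDs with the
#' north-minus-south corporation contrast per sample type, water-type
#' contrasts against municipal drinking water, category contrasts
#' (low-income, high-income, floating), and per-type percent-positive
#' shares.
#'
#' @param trays Long-format tray observations (see [process_samples()]);
#'   must carry `neighborhood`, `category` and `corporation` columns.
#' @param config A [run_config()].
#' @return A list of tibbles: `concentrations` (per sample),
#'   `neighborhood_means`, `corporation_contrasts`, `category_contrasts`
#'   (all three pairwise contrasts), `water_vs_municipal`,
#'   `percent_positive`.
#' @export
replicate_tables <- function(trays, config = run_config()) {
  results <- process_samples(trays, config)
  mult <- config$ci_multiplier

  category_contrasts <- dplyr::bind_rows(
    compare_strata(results, "category", "low_income", "high_income", mult),
    compare_strata(results, "category", "low_income", "floating", mult),
    compare_strata(results, "category", "floating", "high_income", mult)
  )

  water <- results[results$sample_type %in% water_types(), , drop = FALSE]
  municipal <- water[water$sample_type == "municipal_water", , drop = FALSE]
  water_vs_municipal <- water |>
    dplyr::filter(.data$sample_type != "municipal_water") |>
    dplyr::group_by(.data$sample_type) |>
    dplyr::group_modify(function(df, key) {
      pooled <- dplyr::bind_rows(
        dplyr::mutate(df, .grp = "other"),
        dplyr::mutate(municipal, .grp = "municipal")
      )
      pooled$sample_type <- "water"
      out <- compare_strata(pooled, ".grp", "other", "municipal", mult)
      out[setdiff(names(out), "sample_type")]
    }) |>
    dplyr::ungroup()

  list(
    concentrations = results,
    neighborhood_means = summarize_concentrations(results, "neighborhood"),
    corporation_contrasts =
      compare_strata(results, "corporation", "DNCC", "DSCC", mult),
    category_contrasts = category_contrasts,
    water_vs_municipal = water_vs_municipal,
    percent_positive = summarize_concentrations(results)[
      c("sample_type", "n", "percent_positive")]
  )
}
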