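#' Default serial-dilution schemes per sample type
#'
#' Fold-dilutions of the assay fluid loaded on each tray, chosen in the field
#' protocol so that at least one tray per sample falls inside the
#' quantifiable band: drinking and bathing waters undiluted and 1:10; surface
#' water and floodwater 1:10^2 to 1:10^4; drain water 1:10^5 and 1:10^6;
#' street food homogenate 1:10 and 1:10^2; soil eluate 1:10^2 to 1:10^4;
#' latrine swab eluate 1:10 and 1:10^3; produce rinse 1:10 to 1:10^3.
#'
#' @return Named list mapping sample type to a numeric vector of dilution
#'   factors.
#' @export
dilution_schemes <- function() {
  list(
    municipal_water     = c(1, 10),
    non_municipal_water = c(1, 10),
    bathing_water       = c(1, 10),
    surface_water       = c(1e2, 1e3, 1e4),
    floodwater          = c(1e2, 1e3, 1e4),
    drain_water         = c(1e5, 1e6),
    street_food         = c(10, 1e2),
    soil                = c(1e2, 1e3, 1e4),
    latrine_swab        = c(10, 1e3),
    produce             = c(10, 1e2, 1e3)
  )
}

#' Run configuration
#'
#' Collects every numeric constant and switch of the pipeline in one
#' auditable object: tray geometry, matrix processing volumes, the censoring
#' substitution constants (0.5 and 2419.6 MPN per tray), the per-type
#' dilution schemes, the averaging scale for multi-dilution samples, the
#' confidence-interval multiplier for group contrasts, and the study seed.
#'
#' @param geometry A [tray_geometry()].
#' @param matrix A [matrix_metadata()].
#' @param lower_sub,upper_sub Substitution constants for nondetect /
#'   overrange trays (MPN per tray).
#' @param schemes Dilution schemes, as from [dilution_schemes()].
#' @param average `"arithmetic"` (protocol default) or `"geometric"`
#'   averaging across quantifiable trays.
#' @param ci_multiplier Multiplier for contrast confidence intervals (1.96 =
#'   normal 95%; set `NULL` to use the t quantile).
#' @param seed Integer study seed for simulation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = tray_geometry(),
                       matrix = matrix_metadata(),
                       lower_sub = 0.5, upper_sub = 2419.6,
                       schemes = dilution_schemes(),
                       average = c("arithmetic", "geometric"),
                       ci_multiplier = 1.96,
                       seed = 1L) {
  average <- match.arg(average)
  stopifnot(lower_sub > 0, upper_sub > lower_sub, length(schemes) > 0)
  if (!all(vapply(schemes, length, integer(1)) >= 1)) {
    stop("every dilution scheme must list at least one dilution",
         call. = FALSE)
  }
  structure(
    list(geometry = geometry, matrix = matrix, lower_sub = lower_sub,
         upper_sub = upper_sub, schemes = schemes, average = average,
         ci_multiplier = ci_multiplier, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", config_hash(x), "\n")
  cat(sprintf("  substitutions: <LOD -> %g, >ULOQ -> %g MPN/tray\n",
              x$lower_sub, x$upper_sub))
  cat(sprintf("  averaging: %s; CI multiplier: %s; seed: %d\n",
              x$average,
              if (is.null(x$ci_multiplier)) "t quantile" else x$ci_multiplier,
              x$seed))
  invisible(x)
}

#' Hash of a run configuration
#'
#' Stable content hash echoed into output headers so that any artifact can
#' be traced to the exact configuration that produced it.
#'
#' @param config A [run_config()].
#' @return A hexadecimal string.
#' @export
config_hash <- function(config = run_config()) {
  rlang::hash(config)
}
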