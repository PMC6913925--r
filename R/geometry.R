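#' Tray geometry for MPN enumeration
#'
#' Describes the well layout of a defined-substrate enumeration tray: how many
#' wells of each size class it has, the sample volume each well receives, and
#' the reference volume over which the MPN is reported. The default preset is
#' the 97-well Quanti-Tray 2000 (49 large wells of 1.86 mL and 48 small wells
#' of 0.186 mL, partitioning a 100 mL sample), whose quantifiable range is
#' >1 to 2419.6 MPN per tray. The geometry is a configuration object so that
#' other tray formats (e.g. a single-well-class tray) can be analyzed with the
#' same machinery.
#'
#' @param n_large Number of large wells.
#' @param n_small Number of small wells (may be 0 for single-class trays).
#' @param v_large Volume of sample in each large well, mL.
#' @param v_small Volume of sample in each small well, mL.
#' @param reference_volume Volume, in mL, over which the MPN is reported
#'   (100 mL for the default preset, so estimates read as MPN/100 mL of
#'   assayed fluid).
#'
#' @return An object of class `tray_geometry`.
#' @examples
#' tray_geometry()                      # Quanti-Tray 2000 preset
#' tray_geometry(n_large = 51, n_small = 0, v_large = 1.96)
#' @export
tray_geometry <- function(n_large = 49, n_small = 48,
                          v_large = 1.86, v_small = 0.186,
                          reference_volume = 100) {
  stopifnot(
    length(n_large) == 1, length(n_small) == 1,
    length(v_large) == 1, length(v_small) == 1,
    length(reference_volume) == 1
  )
  if (n_large < 1 || n_large != round(n_large)) {
    stop("`n_large` must be a positive whole number", call. = FALSE)
  }
  if (n_small < 0 || n_small != round(n_small)) {
    stop("`n_small` must be a non-negative whole number", call. = FALSE)
  }
  if (v_large <= 0 || reference_volume <= 0) {
    stop("well and reference volumes must be positive", call. = FALSE)
  }
  if (n_small > 0 && v_small <= 0) {
    stop("`v_small` must be positive when the tray has small wells",
         call. = FALSE)
  }
  structure(
    list(
      n_large = as.integer(n_large), n_small = as.integer(n_small),
      v_large = v_large, v_small = if (n_small > 0) v_small else 0,
      reference_volume = reference_volume
    ),
    class = "tray_geometry"
  )
}

#' @export
print.tray_geometry <- function(x, ...) {
  cat(sprintf(
    "<tray_geometry> %d x %.3g mL large wells + %d x %.3g mL small wells; MPN per %g mL\n",
    x$n_large, x$v_large, x$n_small, x$v_small, x$reference_volume
  ))
  invisible(x)
}

# Total sample volume loaded across all wells, mL.
tray_total_volume <- function(geometry) {
  geometry$n_large * geometry$v_large + geometry$n_small * geometry$v_small
}

#' Validate a well-count observation against a tray geometry
#'
#' @param p_large,p_small Counts of positive (fluorescing) large and small
#'   wells.
#' @param geometry A [tray_geometry()].
#' @return Invisibly, a list with the validated integer counts.
#' @keywords internal
validate_tray_counts <- function(p_large, p_small, geometry) {
  if (length(p_large) != 1 || length(p_small) != 1 ||
      is.na(p_large) || is.na(p_small) ||
      p_large != round(p_large) || p_small != round(p_small)) {
    stop("positive-well counts must be single whole numbers", call. = FALSE)
  }
  if (p_large < 0 || p_large > geometry$n_large) {
    stop(sprintf("`p_large` must lie in [0, %d]", geometry$n_large),
         call. = FALSE)
  }
  if (p_small < 0 || p_small > geometry$n_small) {
    stop(sprintf("`p_small` must lie in [0, %d]", geometry$n_small),
         call. = FALSE)
  }
  invisible(list(p_large = as.integer(p_large), p_small = as.integer(p_small)))
}
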