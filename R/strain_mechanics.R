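#' Uniaxial Green-Lagrange strain from initial and final length
#'
#' With shear neglected, the axial Lagrangian strain reduces to
#' \deqn{E = u/X + \frac{1}{2}(u/X)^2}
#' where \eqn{X} is the initial length and \eqn{u} the change in length.
#' Equivalently \eqn{E = (\lambda^2 - 1)/2} for stretch ratio
#' \eqn{\lambda = L/X}.
#'
#' @param initial_length,final_length positive lengths in the same unit
#'   (vectorized).
#' @return dimensionless Lagrangian strain.
#' @examples
#' axial_lagrangian_strain(1.5, 1.8)  # 0.22
#' @export
axial_lagrangian_strain <- function(initial_length, final_length) {
  if (any(!is.finite(initial_length)) || any(!is.finite(final_length)) ||
      any(initial_length <= 0) || any(final_length <= 0))
    stop("invalid measurement: lengths must be finite and positive")
  r <- (final_length - initial_length) / initial_length
  r + 0.5 * r^2
}

#' Stretch ratio corresponding to a Lagrangian strain
#'
#' Inverse of \code{\link{axial_lagrangian_strain}}:
#' \eqn{\lambda = \sqrt{1 + 2E}}. Used by the synthetic generator to deform
#' fiducial dots so that the implied strain is exact.
#'
#' @param E Lagrangian strain, must exceed -0.5.
#' @return stretch ratio \eqn{\lambda > 0}.
#' @export
lagrangian_stretch <- function(E) {
  if (any(E <= -0.5)) stop("strain must exceed -0.5 for a real stretch ratio")
  sqrt(1 + 2 * E)
}

#' Per-well equibiaxial strain from replicate dot measurements
#'
#' Each replicate provides pre/post width and height of the stamped fiducial
#' dot. E_xx is computed from widths, E_yy from heights, each averaged over
#' replicates; the well strain E is the mean of E_xx and E_yy. The standard
#' error is that of the per-replicate E values (sample sd, n-1).
#'
#' @param measurements data.frame with columns \code{pre_width},
#'   \code{pre_height}, \code{post_width}, \code{post_height} and optionally
#'   \code{unit} (must be constant) and \code{well}.
#' @return one-row data.frame: \code{well, Exx, Eyy, E, se, n}.
#' @export
well_strain <- function(measurements) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0)
    stop("at least one replicate measurement is required")
  need <- c("pre_width", "pre_height", "post_width", "post_height")
  if (!all(need %in% names(measurements)))
    stop("missing columns: ", paste(setdiff(need, names(measurements)), collapse = ", "))
  if ("unit" %in% names(measurements) &&
      length(unique(measurements$unit)) > 1)
    stop("mixed units within a well")
  exx <- axial_lagrangian_strain(measurements$pre_width, measurements$post_width)
  eyy <- axial_lagrangian_strain(measurements$pre_height, measurements$post_height)
  e_rep <- (exx + eyy) / 2
  n <- length(e_rep)
  se <- if (n > 1) stats::sd(e_rep) / sqrt(n) else 0
  data.frame(
    well = if ("well" %in% names(measurements)) measurements$well[1] else NA_character_,
    Exx = mean(exx), Eyy = mean(eyy), E = mean(e_rep),
    se = se, n = n, stringsAsFactors = FALSE)
}

#' Per-well strain map for a whole plate
#'
#' Computes \code{\link{well_strain}} for every measured well, separating
#' control wells from injured wells. Measurements in excluded wells are
#' dropped with a warning.
#'
#' @param measurements data.frame of dot measurements with a \code{well}
#'   column (see \code{\link{well_strain}}).
#' @param layout a \code{\link{plate_layout}}.
#' @return data.frame with one row per measured well: \code{well, Exx, Eyy,
#'   E, se, n, is_control}.
#' @export
plate_strain_map <- function(measurements, layout = plate_layout()) {
  stopifnot(inherits(layout, "plate_layout"))
  if (!"well" %in% names(measurements)) stop("measurements need a 'well' column")
  excl <- measurements$well %in% layout$excluded_wells
  if (any(excl)) {
    warning(sum(excl), " measurements in excluded wells dropped")
    measurements <- measurements[!excl, , drop = FALSE]
  }
  unknown <- setdiff(unique(measurements$well), layout$wells)
  if (length(unknown))
    stop("unknown wells: ", paste(unknown, collapse = ", "))
  out <- do.call(rbind, lapply(split(measurements, measurements$well), well_strain))
  out$is_control <- out$well %in% layout$control_wells
  rownames(out) <- NULL
  out[order(match(out$well, layout$wells)), , drop = FALSE]
}

#' Distribution of strain across wells (and plates)
#'
#' Population statistics of per-well mean strains: across-well mean and
#' sample (n-1) standard deviation. When a \code{plate} column is present and
#' wells recur on multiple plates, the average per-well sd across plates is
#' also reported (the repeatability of a given well location over tests).
#'
#' @param well_strains data.frame from \code{\link{plate_strain_map}} (or any
#'   frame with columns \code{well} and \code{E}; optional \code{plate}).
#' @param include_controls logical; controls are excluded from the injury
#'   statistics by default when an \code{is_control} column is present.
#' @return list with \code{mean}, \code{sd}, \code{n_wells} and (if
#'   applicable) \code{mean_within_well_sd}.
#' @export
summarize_strain_distribution <- function(well_strains, include_controls = FALSE) {
  ws <- well_strains
  if (!include_controls && "is_control" %in% names(ws))
    ws <- ws[!ws$is_control, , drop = FALSE]
  if (nrow(ws) < 2) stop("need at least 2 wells to summarize a distribution")
  out <- list(mean = mean(ws$E), sd = stats::sd(ws$E), n_wells = nrow(ws))
  if ("plate" %in% names(ws) && anyDuplicated(ws$well)) {
    per_well_sd <- tapply(ws$E, ws$well, function(e)
      if (length(e) > 1) stats::sd(e) else NA_real_)
    out$mean_within_well_sd <- mean(per_well_sd, na.rm = TRUE)
  }
  out
}

#' Relationship between stage displacement and membrane strain
#'
#' Ordinary least-squares line through (displacement, mean strain) pairs
#' across displacement levels. Levels whose strain falls below a near-zero
#' threshold are flagged as negligible: the membrane only engages the posts
#' after a finite displacement, so the lowest amplitude typically produces
#' essentially no strain and distorts a naive linear fit.
#'
#' @param displacement stage displacement amplitudes (mm).
#' @param strain mean Lagrangian strain at each amplitude.
#' @param negligible_threshold strains below this are flagged (default 0.02).
#' @return list with \code{slope}, \code{intercept}, \code{residuals},
#'   \code{negligible} (logical per level) and the underlying \code{lm} fit.
#' @export
displacement_strain_curve <- function(displacement, strain,
                                      negligible_threshold = 0.02) {
  if (length(displacement) != length(strain))
    stop("displacement and strain must have equal length")
  if (length(unique(displacement)) < 2)
    stop("need at least 2 distinct displacement levels")
  fit <- stats::lm(strain ~ displacement)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = unname(stats::residuals(fit)),
       negligible = strain < negligible_threshold,
       fit = fit)
}
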