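# Synthetic-data generators: fiducial-dot deformations from a prescribed
# strain field, well-metric tables from the logistic dose-response model, and
# rendered fluorescence channels from a parametric culture scene. All
# generators are seeded and deterministic; every output is paired with its
# ground truth so the analysis modules can be validated by round trip.

#' Specification of a plate strain field
#'
#' @param mode "aligned" (no systematic variation across the plate) or
#'   "misaligned" (linear left-to-right gradient across columns, as produced
#'   by a post array without alignment set screws).
#' @param mean_strain plate-mean Lagrangian strain of injured wells.
#' @param well_sd random well-to-well sd of true strain.
#' @param replicate_sd sd of replicate-to-replicate measurement variation
#'   (expressed in strain units).
#' @param gradient strain increment per column index (misaligned mode only;
#'   forced to 0 in aligned mode).
#' @param seed integer seed.
#' @return list of class \code{strain_field_spec}.
#' @export
strain_field_spec <- function(mode = c("aligned", "misaligned"),
                              mean_strain = 0.45, well_sd = 0.051,
                              replicate_sd = 0, gradient = 0.04, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(mean_strain >= 0, well_sd >= 0, replicate_sd >= 0)
  if (mode == "aligned") gradient <- 0
  structure(list(mode = mode, mean_strain = mean_strain, well_sd = well_sd,
                 replicate_sd = replicate_sd, gradient = gradient,
                 seed = as.integer(seed)), class = "strain_field_spec")
}

# Draw values until all exceed -0.5 (a real stretch ratio exists); rejected
# draws are logged via message().
rtrunc_strain <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= -0.5)
  while (length(bad)) {
    message(length(bad), " strain draw(s) implied a negative stretch ratio; resampled")
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= -0.5)
  }
  x
}

#' Generate fiducial-dot measurements for a plate
#'
#' Each non-excluded well receives a true strain drawn from the strain-field
#' spec (control wells receive exactly zero), and \code{n_replicates} pre/post
#' width-height pairs are emitted whose implied Green-Lagrange strain equals
#' the well's (replicate-perturbed) true strain: post dimension =
#' pre x sqrt(1 + 2E), equal in x and y (equibiaxial, no shear).
#'
#' @param layout a \code{\link{plate_layout}}.
#' @param spec a \code{\link{strain_field_spec}}.
#' @param pre_dot_diameter stamped dot diameter (mm), default 1.5.
#' @param n_replicates independent measurements per well, default 5.
#' @return list with \code{measurements} (data.frame well, replicate,
#'   pre_width, pre_height, post_width, post_height, unit) and \code{truth}
#'   (data.frame well, strain, is_control).
#' @export
gen_dot_measurements <- function(layout = plate_layout(),
                                 spec = strain_field_spec(),
                                 pre_dot_diameter = 1.5, n_replicates = 5) {
  stopifnot(inherits(layout, "plate_layout"), inherits(spec, "strain_field_spec"),
            pre_dot_diameter > 0, n_replicates >= 1)
  set.seed(spec$seed)
  wells <- setdiff(layout$wells, layout$excluded_wells)
  is_control <- wells %in% layout$control_wells
  rc <- well_row_col(wells)
  base <- rep(spec$mean_strain, length(wells)) +
    if (spec$mode == "misaligned") spec$gradient * (rc$col - mean(rc$col)) else 0
  true_strain <- vapply(seq_along(wells), function(i)
    rtrunc_strain(1, base[i], spec$well_sd), numeric(1))
  true_strain[is_control] <- 0
  meas <- do.call(rbind, lapply(seq_along(wells), function(i) {
    e_rep <- if (is_control[i]) rep(0, n_replicates) else
      rtrunc_strain(n_replicates, true_strain[i], spec$replicate_sd)
    lam <- lagrangian_stretch(e_rep)
    data.frame(well = wells[i], replicate = seq_len(n_replicates),
               pre_width = pre_dot_diameter, pre_height = pre_dot_diameter,
               post_width = pre_dot_diameter * lam,
               post_height = pre_dot_diameter * lam,
               unit = "mm", stringsAsFactors = FALSE)
  }))
  list(measurements = meas,
       truth = data.frame(well = wells, strain = true_strain,
                          is_control = is_control, stringsAsFactors = FALSE))
}

#' Noise sd reproducing a target coefficient of determination
#'
#' For additive Gaussian well noise around the logistic curve, the expected
#' R-squared of a perfect fit is Var(model)/(Var(model) + sd^2); inverting
#' gives sd = sqrt(Var(model) (1 - R2) / R2), with Var taken over the model
#' values at the design strains.
#'
#' @param params \code{\link{logistic_params}}.
#' @param strains design strain values.
#' @param r_squared target R-squared in (0, 1].
#' @return noise standard deviation in metric units.
#' @export
noise_sd_for_r2 <- function(params, strains, r_squared) {
  stopifnot(r_squared > 0, r_squared <= 1)
  yhat <- logistic_eval(params, strains)
  sqrt(stats::var(yhat) * (1 - r_squared) / r_squared)
}

#' Specification for generating a well-metrics table
#'
#' @param params data.frame with columns \code{metric, y0, yf, k, Et} (and
#'   optionally \code{r_squared} used to calibrate noise when
#'   \code{noise_sd} is NULL); default \code{\link{injury_metric_params}}.
#' @param noise_sd named numeric vector of per-metric noise sd, or NULL to
#'   calibrate each metric's sd to its \code{r_squared}.
#' @param well_strains numeric vector of true strains for the non-control,
#'   non-excluded wells (recycled); default evenly spaced on [0.02, 0.62].
#' @param seed integer seed.
#' @return list of class \code{dose_response_spec}.
#' @export
dose_response_spec <- function(params = injury_metric_params(),
                               noise_sd = NULL, well_strains = NULL,
                               seed = 1L) {
  stopifnot(all(c("metric", "y0", "yf", "k", "Et") %in% names(params)),
            all(params$k > 0), all(params$Et > 0))
  if (!is.null(noise_sd)) {
    stopifnot(all(noise_sd >= 0), !is.null(names(noise_sd)))
  } else if (!"r_squared" %in% names(params)) {
    stop("supply noise_sd or a params table with an r_squared column")
  }
  structure(list(params = params, noise_sd = noise_sd,
                 well_strains = well_strains, seed = as.integer(seed)),
            class = "dose_response_spec")
}

#' Generate a well-metrics table from the logistic dose-response model
#'
#' One record per non-excluded well: the well's true strain plus each metric
#' evaluated on the logistic curve with additive Gaussian noise. Control
#' wells are assigned strain 0. Regeneration with the same spec and seed is
#' bit-identical.
#'
#' @param layout a \code{\link{plate_layout}}.
#' @param spec a \code{\link{dose_response_spec}}.
#' @return data.frame: well, is_control, strain, one column per metric.
#' @export
gen_plate_metrics <- function(layout = plate_layout(),
                              spec = dose_response_spec()) {
  stopifnot(inherits(layout, "plate_layout"), inherits(spec, "dose_response_spec"))
  set.seed(spec$seed)
  wells <- setdiff(layout$wells, layout$excluded_wells)
  is_control <- wells %in% layout$control_wells
  n_inj <- sum(!is_control)
  ws <- spec$well_strains
  if (is.null(ws)) ws <- seq(0.02, 0.62, length.out = n_inj)
  strain <- numeric(length(wells))
  strain[!is_control] <- rep_len(ws, n_inj)
  out <- data.frame(well = wells, is_control = is_control, strain = strain,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(spec$params))) {
    row <- spec$params[i, ]
    p <- logistic_params(row$y0, row$yf, row$k, row$Et)
    sd_i <- if (!is.null(spec$noise_sd)) spec$noise_sd[[row$metric]] else
      noise_sd_for_r2(p, strain, row$r_squared)
    out[[row$metric]] <- logistic_eval(p, strain) + stats::rnorm(length(strain), 0, sd_i)
  }
  out
}

#' Simulate a multi-plate injury experiment
#'
#' Convenience wrapper emulating the full dose-response study: a prescribed
#' number of injured wells with true strains evenly spread over a range (the
#' spectrum produced by combining several stage-displacement levels with the
#' misaligned plate gradient), plus zero-strain control wells, with per-metric
#' noise calibrated so a perfect fit would reproduce each metric's reference
#' R-squared.
#'
#' @param params parameter table as in \code{\link{dose_response_spec}}.
#' @param n_injured number of injured wells (default 152).
#' @param n_control number of zero-strain control wells (default 40: eight
#'   control wells on each of five plates).
#' @param strain_range range of injured-well true strains.
#' @param seed integer seed.
#' @return data.frame: well id, is_control, strain, one column per metric.
#' @export
simulate_injury_experiment <- function(params = injury_metric_params(),
                                       n_injured = 152, n_control = 40,
                                       strain_range = c(0.02, 0.62),
                                       seed = 1L) {
  set.seed(as.integer(seed))
  strain <- c(seq(strain_range[1], strain_range[2], length.out = n_injured),
              rep(0, n_control))
  out <- data.frame(
    well = sprintf("w%03d", seq_along(strain)),
    is_control = c(rep(FALSE, n_injured), rep(TRUE, n_control)),
    strain = strain, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    p <- logistic_params(row$y0, row$yf, row$k, row$Et)
    sd_i <- noise_sd_for_r2(p, strain, row$r_squared)
    out[[row$metric]] <- logistic_eval(p, strain) + stats::rnorm(length(strain), 0, sd_i)
  }
  out
}
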