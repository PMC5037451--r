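#' Four-parameter generalized logistic model parameters
#'
#' Parameters of the sigmoid used to describe how each injury metric varies
#' with strain: \code{y0} is the zero-strain value of the metric, \code{yf}
#' the value the metric asymptotically approaches at high strain, \code{k} a
#' dimensionless rate constant governing the sharpness of the transition, and
#' \code{Et} the transition strain at which the metric is halfway between
#' \code{y0} and \code{yf}.
#'
#' @param y0,yf asymptotes in metric units.
#' @param k rate constant, > 0.
#' @param Et transition strain, > 0.
#' @return a named list of class \code{logistic_params}.
#' @export
logistic_params <- function(y0, yf, k, Et) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (!is.finite(Et) || Et <= 0) stop("Et must be positive")
  structure(list(y0 = y0, yf = yf, k = k, Et = Et), class = "logistic_params")
}

#' Evaluate the generalized logistic dose-response curve
#'
#' \deqn{y(E) = y_f + \frac{y_0 - y_f}{1 + \exp(k (E - E_t))}}
#' At \eqn{E = E_t} the curve passes exactly through \eqn{(y_0 + y_f)/2}; as
#' \eqn{E \to \infty} it approaches \eqn{y_f}. \eqn{y(0) = y_0} holds to
#' within \eqn{(y_0-y_f) e^{-k E_t}}, negligible whenever \eqn{k E_t \gg 1}
#' as in all fitted metrics here.
#'
#' @param params a \code{\link{logistic_params}} (or list with y0, yf, k, Et).
#' @param E strain value(s).
#' @return metric value(s).
#' @examples
#' p <- logistic_params(y0 = 141, yf = 31.55, k = 14.43, Et = 0.339)
#' logistic_eval(p, p$Et) == (p$y0 + p$yf) / 2
#' @export
logistic_eval <- function(params, E) {
  params$yf + (params$y0 - params$yf) / (1 + exp(params$k * (E - params$Et)))
}

auto_init <- function(strain, value) {
  ord <- order(strain)
  s <- strain[ord]; v <- value[ord]
  n <- length(s)
  lo <- v[seq_len(max(1, floor(n / 3)))]
  hi <- v[seq(n - max(1, floor(n / 3)) + 1, n)]
  y0 <- mean(lo); yf <- mean(hi)
  mid <- (y0 + yf) / 2
  Et <- s[which.min(abs(v - mid))]
  if (!is.finite(Et) || Et <= 0) Et <- stats::median(s[s > 0], na.rm = TRUE)
  list(y0 = y0, yf = yf, k = 15, Et = max(Et, 1e-3))
}

#' Fit the generalized logistic model by Levenberg-Marquardt
#'
#' Nonlinear least squares via \code{minpack.lm::nlsLM}. Start values are
#' either supplied or derived automatically: \code{y0} from the mean of the
#' lowest-strain tertile, \code{yf} from the highest-strain tertile,
#' \code{Et} from the strain whose observed value is nearest the midpoint,
#' and \code{k = 15}. 95\% confidence intervals are asymptotic
#' (Jacobian-based covariance times a t quantile), matching the output of
#' standard statistics packages. Non-convergence and degenerate inputs are
#' flagged, not raised.
#'
#' @param strain,value per-well strain and metric value (equal length, >= 5
#'   points).
#' @param init optional \code{\link{logistic_params}} start values.
#' @param conf_level confidence level for the parameter intervals.
#' @return object of class \code{logistic_fit}: list with \code{params}
#'   (estimates), \code{ci} (matrix with lower/upper columns), \code{se},
#'   \code{r_squared}, \code{converged}, \code{iterations}, \code{n},
#'   \code{message} and the underlying \code{nls} object (when converged).
#' @export
fit_logistic <- function(strain, value, init = NULL, conf_level = 0.95) {
  ok <- is.finite(strain) & is.finite(value)
  strain <- strain[ok]; value <- value[ok]
  if (length(strain) < 5) stop("need at least 5 data points")
  failed <- function(msg) structure(list(
    params = NULL, ci = NULL, se = NULL, r_squared = NA_real_,
    converged = FALSE, iterations = 0L, n = length(strain),
    message = msg, fit = NULL), class = "logistic_fit")
  if (stats::sd(value) == 0) return(failed("degenerate data: constant metric"))
  start <- if (is.null(init)) auto_init(strain, value) else
    init[c("y0", "yf", "k", "Et")]
  dat <- data.frame(E = strain, y = value)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ yf + (y0 - yf) / (1 + exp(k * (E - Et))),
                      data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(est)
  df <- length(strain) - length(est)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((value - mean(value))^2)
  structure(list(
    params = logistic_params(est[["y0"]], est[["yf"]], est[["k"]], abs(est[["Et"]])),
    ci = ci, se = se,
    r_squared = 1 - ss_res / ss_tot,
    converged = fit$convInfo$isConv %||% TRUE,
    iterations = fit$convInfo$finIter %||% NA_integer_,
    n = length(strain), message = "converged", fit = fit),
    class = "logistic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("logistic fit: NOT converged (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  p <- x$params
  est <- c(y0 = p$y0, yf = p$yf, k = p$k, Et = p$Et)
  tab <- data.frame(estimate = est,
                    lower = x$ci[names(est), "lower"],
                    upper = x$ci[names(est), "upper"])
  print(round(tab, 4))
  cat(sprintf("R-squared %.4f  (n = %d wells)\n", x$r_squared, x$n))
  invisible(x)
}

#' Fit the logistic model to every injury metric in a well table
#'
#' Applies \code{\link{fit_logistic}} to each metric column against the
#' \code{strain} column. Control wells (strain 0) contribute as zero-strain
#' observations. Per-metric failures are reported per metric and do not abort
#' the batch; flat or failed metrics are excluded from the transition-strain
#' range summary.
#'
#' @param well_table data.frame with a \code{strain} column and one column
#'   per metric (non-metric bookkeeping columns \code{well}, \code{plate},
#'   \code{is_control} are ignored).
#' @param metrics character vector of metric column names; default all
#'   non-bookkeeping columns.
#' @return list with \code{fits} (named list of \code{logistic_fit}),
#'   \code{summary} (data.frame metric, y0, yf, k, Et, CI bounds, r_squared,
#'   converged) and \code{Et_range} (min/max fitted Et over converged fits).
#' @export
fit_all_metrics <- function(well_table, metrics = NULL) {
  if (!"strain" %in% names(well_table)) stop("well_table needs a 'strain' column")
  if (is.null(metrics))
    metrics <- setdiff(names(well_table),
                       c("well", "plate", "strain", "is_control"))
  if (!length(metrics)) stop("no metric columns found")
  fits <- lapply(metrics, function(m)
    tryCatch(fit_logistic(well_table$strain, well_table[[m]]),
             error = function(e) structure(list(
               params = NULL, ci = NULL, se = NULL, r_squared = NA_real_,
               converged = FALSE, iterations = 0L, n = nrow(well_table),
               message = conditionMessage(e), fit = NULL),
               class = "logistic_fit")))
  names(fits) <- metrics
  rows <- lapply(metrics, function(m) {
    f <- fits[[m]]
    if (f$converged) {
      p <- f$params
      data.frame(metric = m, y0 = p$y0, yf = p$yf, k = p$k, Et = p$Et,
                 y0_lo = f$ci["y0", "lower"], y0_hi = f$ci["y0", "upper"],
                 yf_lo = f$ci["yf", "lower"], yf_hi = f$ci["yf", "upper"],
                 k_lo = f$ci["k", "lower"], k_hi = f$ci["k", "upper"],
                 Et_lo = f$ci["Et", "lower"], Et_hi = f$ci["Et", "upper"],
                 r_squared = f$r_squared, converged = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(metric = m, y0 = NA_real_, yf = NA_real_, k = NA_real_,
                 Et = NA_real_, y0_lo = NA_real_, y0_hi = NA_real_,
                 yf_lo = NA_real_, yf_hi = NA_real_, k_lo = NA_real_,
                 k_hi = NA_real_, Et_lo = NA_real_, Et_hi = NA_real_,
                 r_squared = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  summary <- do.call(rbind, rows)
  ets <- summary$Et[summary$converged]
  list(fits = fits, summary = summary,
       Et_range = if (length(ets)) range(ets) else c(NA_real_, NA_real_))
}

#' Reference dose-response parameters for the nine injury metrics
#'
#' Default ground-truth parameter set used by the synthetic-data module: for
#' each of the nine injury metrics of the assay, the generalized-logistic
#' parameters (y0, yf, k, Et) and the coefficient of determination used to
#' calibrate simulation noise. These are the published estimates from the
#' original 96-well characterization of this injury model, treated here as
#' generating truth for parameter-recovery simulations.
#'
#' @return data.frame with columns \code{metric, y0, yf, k, Et, r_squared}.
#' @export
injury_metric_params <- function() {
  data.frame(
    metric = c("neurite_length_per_cell", "cell_viability",
               "processes_per_cell", "total_neurite_length",
               "branches_per_cell", "total_processes",
               "viable_cells_per_image", "total_branches",
               "dead_cells_per_image"),
    y0 = c(141, 78.44, 3.36, 43411, 2.462, 1063, 312.8, 801.5, 271.1),
    yf = c(31.55, 18.91, 1.327, 2645, 0.199, 103.3, 77.03, 15.94, 528.2),
    k = c(14.43, 18.43, 16.43, 16.46, 15, 17.24, 17.8, 15.8, 24.58),
    Et = c(0.339, 0.357, 0.353, 0.322, 0.334, 0.337, 0.361, 0.305, 0.356),
    r_squared = c(0.834, 0.828, 0.828, 0.819, 0.745, 0.708, 0.689, 0.589, 0.459),
    stringsAsFactors = FALSE)
}
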