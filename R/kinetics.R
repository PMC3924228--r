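#' Growth rate from an OD600 time course
#'
#' The specific growth rate between consecutive samples,
#' \eqn{GR_t = \ln(OD_t / OD_{t-1}) / \Delta t} (units 1/hr), the
#' dimensionally consistent log-ratio form; the raw ratio
#' \eqn{(OD_t/OD_{t-1})/\Delta t} is available for comparison.
#'
#' @param times sampling times, hr, strictly increasing.
#' @param od600 optical densities, > 0.
#' @param method `"log"` (default) or `"ratio"`.
#' @return data.frame with `time` (right endpoint of each interval) and
#'   `gr` (1/hr); `length(times) - 1` rows.
#' @export
growth_rate <- function(times, od600, method = c("log", "ratio")) {
  method <- match.arg(method)
  if (length(times) != length(od600) || length(times) < 2)
    mc_stop("validation", "need aligned times and od600 with >= 2 points")
  if (any(diff(times) <= 0))
    mc_stop("validation", "times must be strictly increasing")
  bad <- which(od600 <= 0)
  if (length(bad))
    mc_stop("nonpositive-od", paste("OD must be > 0 for the log ratio; first offender index", bad[1]))
  dt <- diff(times)
  r <- od600[-1] / od600[-length(od600)]
  gr <- if (method == "log") log(r) / dt else r / dt
  data.frame(time = times[-1], gr = gr)
}

#' Normalize a substrate time course to biomass
#'
#' Divides substrate concentration pointwise by OD600 (interpolating the
#' OD curve linearly onto the substrate time grid when the grids differ;
#' no extrapolation) and rescales so the series starts at 1 — the
#' normalization applied to substrate consumption curves before decay
#' fitting.
#'
#' @param times sampling times of the substrate series, hr.
#' @param conc substrate concentrations.
#' @param od_times,od600 the OD600 curve (defaults: same grid as `times`).
#' @param rescale divide by the first normalized value (default `TRUE`).
#' @param pointwise divide by the OD at each time point (default); if
#'   `FALSE`, divide by the final OD only.
#' @return data.frame `time`, `value`.
#' @export
normalize_to_biomass <- function(times, conc, od_times = times, od600,
                                 rescale = TRUE, pointwise = TRUE) {
  od <- if (identical(od_times, times)) od600
        else interp_series(od_times, od600, times)
  if (any(od <= 0)) mc_stop("nonpositive-od", "OD must be > 0")
  v <- if (pointwise) conc / od else conc / od[length(od)]
  if (rescale) {
    if (v[1] == 0) mc_stop("validation", "first value is zero; cannot rescale")
    v <- v / v[1]
  }
  data.frame(time = times, value = v)
}

#' Fit a one-phase exponential decay
#'
#' Nonlinear least squares for
#' \eqn{y(t) = plateau + (y_0 - plateau) e^{-K t}}: the conventional
#' one-phase decay used for biomass-normalized substrate uptake curves.
#' K (1/hr) is the uptake rate constant — larger K, faster uptake — and
#' the half-life \eqn{\ln 2 / K} is the time at which the curve reaches
#' the midpoint between `y0` and `plateau`.
#'
#' Start values come from a log-linear regression on `y - min(y)`;
#' the fit uses Levenberg–Marquardt with K bounded positive.
#'
#' @param t times, hr.
#' @param y observed values; >= 4 points, not all equal.
#' @param fix_plateau_zero force `plateau = 0` (two-parameter fit).
#' @return a `decay_fit`: list with `y0`, `plateau`, `K` (1/hr),
#'   `half_life` (hr), `rss`, `converged`, `fitted` (function of t).
#' @export
fit_one_phase_decay <- function(t, y, fix_plateau_zero = FALSE) {
  if (length(t) != length(y) || length(t) < 4)
    mc_stop("validation", "need >= 4 aligned points")
  if (diff(range(y)) == 0)
    mc_stop("no-decay", "series is constant; nothing to fit")
  ymin <- min(y); yspan <- diff(range(y))
  pos <- y - ymin + 0.05 * yspan
  lf <- stats::lm(log(pos) ~ t)
  K0 <- max(-stats::coef(lf)[2], 1e-3)
  y00 <- y[1]
  p00 <- if (fix_plateau_zero) 0 else ymin
  fit <- tryCatch({
    if (fix_plateau_zero)
      minpack.lm::nlsLM(y ~ y0 * exp(-K * t),
                        start = list(y0 = y00, K = K0),
                        lower = c(y0 = -Inf, K = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ plateau + (y0 - plateau) * exp(-K * t),
                        start = list(plateau = p00, y0 = y00, K = K0),
                        lower = c(plateau = -Inf, y0 = -Inf, K = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(y0 = NA_real_, plateau = NA_real_, K = NA_real_,
                          half_life = NA_real_, rss = NA_real_,
                          converged = FALSE, fitted = NULL),
                     class = "decay_fit"))
  }
  co <- stats::coef(fit)
  K <- unname(co["K"])
  plateau <- if (fix_plateau_zero) 0 else unname(co["plateau"])
  y0 <- unname(co["y0"])
  converged <- isTRUE(fit$convInfo$isConv) && K > 1e-8
  structure(list(
    y0 = y0, plateau = plateau, K = K,
    half_life = log(2) / K,
    rss = sum(stats::residuals(fit)^2),
    converged = converged,
    fitted = function(tt) plateau + (y0 - plateau) * exp(-K * tt)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "one-phase decay: K = %.4g /hr, half-life = %.4g hr, y0 = %.4g, plateau = %.4g (%s)\n",
    x$K, x$half_life, x$y0, x$plateau,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Promoter activity as GFP per OD600
#'
#' Pointwise GFP/OD600 ratios, and optionally the induced/uninduced
#' fold-ratio used to quantify promoter induction.
#'
#' @param times sampling times, hr.
#' @param gfp fluorescence readings.
#' @param od600 matched OD600, > 0.
#' @return data.frame `time`, `activity`.
#' @export
promoter_activity <- function(times, gfp, od600) {
  if (any(od600 <= 0)) mc_stop("nonpositive-od", "OD must be > 0")
  if (length(gfp) != length(od600) || length(times) != length(gfp))
    mc_stop("validation", "series lengths differ")
  data.frame(time = times, activity = gfp / od600)
}

#' @rdname promoter_activity
#' @param induced,uninduced data.frames from [promoter_activity()] on a
#'   shared time grid.
#' @return for `promoter_fold_ratio`: data.frame `time`, `fold`.
#' @export
promoter_fold_ratio <- function(induced, uninduced) {
  if (!isTRUE(all.equal(induced$time, uninduced$time)))
    mc_stop("validation", "induced/uninduced time grids differ")
  if (any(uninduced$activity == 0))
    mc_stop("validation", "uninduced activity contains zeros")
  data.frame(time = induced$time,
             fold = induced$activity / uninduced$activity)
}

#' Standard Ficoll step-gradient layer densities
#'
#' The eight layer densities (g/ml) of the step gradient, heaviest first.
#' @return numeric vector of length 8.
#' @export
ficoll_layer_densities <- function() {
  c(1.19, 1.18, 1.16, 1.14, 1.12, 1.10, 1.08, 1.06)
}

#' Cell density distribution from a Ficoll gradient
#'
#' The fraction of culture OD600 recovered in each density layer,
#' \eqn{CDD_{\rho_i} = OD_{\rho_i} / \sum_i OD_{\rho_i}}, after blank
#' subtraction, plus two summaries: the modal layer density and the
#' OD-weighted mean density \eqn{\sum_i CDD_{\rho_i} \rho_i}.
#'
#' @param layer_od OD600 per layer.
#' @param layer_densities g/ml per layer, default the 8-step gradient of
#'   [ficoll_layer_densities()].
#' @param blank per-layer background (same Ficoll solutions without
#'   cells), subtracted before normalization; negative differences are
#'   clipped to zero with a warning.
#' @return a `density_profile`: list with `layer_densities`, `layer_od`
#'   (blank-subtracted), `cdd`, `modal_density`, `mean_density`.
#' @export
cell_density_distribution <- function(layer_od,
                                      layer_densities = ficoll_layer_densities(),
                                      blank = 0) {
  if (length(layer_od) != length(layer_densities))
    mc_stop("validation", "layer_od and layer_densities lengths differ")
  od <- layer_od - blank
  if (any(od < 0)) {
    warning("negative OD after blank subtraction clipped to 0")
    od <- pmax(od, 0)
  }
  tot <- sum(od)
  if (tot <= 0) mc_stop("empty-gradient", "all layers are zero after blank subtraction")
  cdd <- od / tot
  structure(list(layer_densities = layer_densities, layer_od = od,
                 cdd = cdd,
                 modal_density = layer_densities[which.max(cdd)],
                 mean_density = sum(cdd * layer_densities)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("cell density distribution over", length(x$cdd), "layers\n")
  print(stats::setNames(round(x$cdd, 4), paste0(x$layer_densities, " g/ml")))
  cat(sprintf("modal density %.2f g/ml, OD-weighted mean %.4f g/ml\n",
              x$modal_density, x$mean_density))
  invisible(x)
}

#' Two-sample t-test convenience wrapper
#'
#' Plain Welch two-sample t-test on two numeric vectors, as used for
#' intergroup comparisons of culture measurements; returns the
#' `stats::t.test` object unchanged.
#'
#' @param x,y numeric vectors.
#' @param ... passed to [stats::t.test()].
#' @export
compare_groups <- function(x, y, ...) stats::t.test(x, y, ...)
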