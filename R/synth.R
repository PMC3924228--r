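# Seeded generators for every input the analysis functions consume.
# Each generator draws from its own RNG stream derived from
# (seed, generator name), so adding generators never perturbs existing
# output, and identical calls are byte-identical.

# unbiased multiplicative lognormal noise with coefficient of variation cv
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Noisy plate-reader observations of a batch trajectory
#'
#' Samples a simulated (or analytic) batch trajectory on a regular
#' grid — default every 30 minutes, the usual sampling interval for
#' OD600 time courses — and applies multiplicative lognormal measurement
#' noise to OD and substrate concentrations. The noise default (2% CV)
#' resembles plate-reader variability and is configurable, not
#' data-derived.
#'
#' @param traj a `batch_trajectory` from [simulate_batch()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param interval sampling interval, hr.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @return list with `od` (data.frame time, od600), `concentrations`
#'   (data.frame time, one column per substrate, plus acetate), and
#'   `truth` (the noiseless sampled values).
#' @export
generate_batch_observations <- function(traj, seed, interval = 0.5,
                                        noise_cv = 0.02) {
  subs <- attr(traj, "substrates")
  tt <- seq(min(traj$time), max(traj$time), by = interval)
  truth_od <- interp_series(traj$time, traj$od600, tt)
  truth_conc <- vapply(c(subs, "acetate"),
                       function(s) interp_series(traj$time, traj[[s]], tt),
                       numeric(length(tt)))
  with_stream(seed, "batch_observations", {
    od <- truth_od * lognormal_factor(length(tt), noise_cv)
    conc <- truth_conc * matrix(lognormal_factor(length(truth_conc), noise_cv),
                                nrow(truth_conc))
    list(od = data.frame(time = tt, od600 = od),
         concentrations = data.frame(time = tt, conc, check.names = FALSE),
         truth = list(od = data.frame(time = tt, od600 = truth_od),
                      concentrations = data.frame(time = tt, truth_conc,
                                                  check.names = FALSE)))
  })
}

#' Noisy one-phase-decay observations with known rate constant
#'
#' Closed-form ground truth \eqn{y(t) = plateau + (y_0-plateau)e^{-Kt}}
#' sampled at `n` points with multiplicative lognormal noise — the
#' recovery target for [fit_one_phase_decay()].
#'
#' @param y0,plateau,K true decay parameters (K in 1/hr).
#' @param seed integer seed.
#' @param n number of samples.
#' @param t_max last sampling time, hr.
#' @param noise_cv noise CV (0 = exact).
#' @return data.frame `time`, `value` with attribute `truth`.
#' @export
generate_decay_observations <- function(y0 = 1, plateau = 0, K = 0.5, seed = 1,
                                        n = 20, t_max = 6, noise_cv = 0.02) {
  tt <- seq(0, t_max, length.out = n)
  mu <- plateau + (y0 - plateau) * exp(-K * tt)
  with_stream(seed, "decay_observations", {
    y <- mu * lognormal_factor(n, noise_cv)
    structure(data.frame(time = tt, value = y),
              truth = list(y0 = y0, plateau = plateau, K = K,
                           half_life = log(2) / K))
  })
}

#' Synthetic Ficoll gradient profile with known density center
#'
#' Distributes a Gaussian mass of cells over the discrete gradient
#' layers (weights proportional to the normal density at each layer
#' density times the layer's width in density units), adds a constant
#' Ficoll background plus additive Gaussian read noise, and returns the
#' raw ODs together with the blank column used for background
#' subtraction.
#'
#' @param center true buoyant density center, g/ml; must lie within the
#'   layer range.
#' @param spread Gaussian spread, g/ml; `0` puts all mass in the nearest
#'   layer.
#' @param layers layer densities, default [ficoll_layer_densities()].
#' @param total_od total cell OD600 distributed over the gradient.
#' @param background constant Ficoll blank OD per layer.
#' @param noise_sd additive read noise (OD units) on both sample and
#'   blank.
#' @param seed integer seed.
#' @return list `layer_od` (sample reads), `blank` (blank reads),
#'   `layers`, `truth` (center, spread, expected weights).
#' @export
generate_gradient_profile <- function(center = 1.13, spread = 0.02,
                                      layers = ficoll_layer_densities(),
                                      total_od = 1, background = 0.05,
                                      noise_sd = 0.002, seed = 1) {
  if (center < min(layers) || center > max(layers))
    mc_stop("validation", sprintf(
      "center %.3f g/ml outside the layer range [%.2f, %.2f]",
      center, min(layers), max(layers)))
  ord <- order(layers)
  width <- numeric(length(layers))
  mids <- (layers[ord][-1] + layers[ord][-length(layers)]) / 2
  edges <- c(layers[ord][1] - (mids[1] - layers[ord][1]), mids,
             layers[ord][length(layers)] +
               (layers[ord][length(layers)] - mids[length(mids)]))
  width[ord] <- diff(edges)
  w <- if (spread <= 0) as.numeric(seq_along(layers) ==
                                     which.min(abs(layers - center)))
       else stats::dnorm(layers, center, spread) * width
  w <- w / sum(w)
  with_stream(seed, "gradient_profile", {
    od <- total_od * w + background + stats::rnorm(length(layers), 0, noise_sd)
    blank <- background + stats::rnorm(length(layers), 0, noise_sd)
    list(layer_od = pmax(od, 0), blank = blank, layers = layers,
         truth = list(center = center, spread = spread, weights = w))
  })
}

#' Synthetic promoter-induction time course
#'
#' Paired induced/uninduced GFP and OD600 series emulating a reporter
#' experiment: both cultures grow identically (logistic OD); the induced
#' culture's GFP per OD steps from the basal level to `fold` times basal
#' after the induction time.
#'
#' @param fold true post-induction fold-change of GFP/OD (>= 1).
#' @param onset_hr induction time, hr.
#' @param seed integer seed.
#' @param t_end,interval sampling design, hr.
#' @param basal basal GFP per OD unit.
#' @param noise_cv multiplicative noise CV on GFP and OD.
#' @return list `induced`, `uninduced` (data.frames time, od600, gfp) and
#'   `truth`.
#' @export
generate_induction_timecourse <- function(fold = 3, onset_hr = 1, seed = 1,
                                          t_end = 6, interval = 0.5,
                                          basal = 100, noise_cv = 0.02) {
  if (fold < 1) mc_stop("validation", "fold must be >= 1")
  tt <- seq(0, t_end, by = interval)
  od <- 0.035 + (1 - 0.035) / (1 + exp(-1.5 * (tt - 3)))   # logistic growth
  act <- basal * ifelse(tt > onset_hr, fold, 1)
  with_stream(seed, "induction_timecourse", {
    mk <- function(activity) data.frame(
      time = tt,
      od600 = od * lognormal_factor(length(tt), noise_cv),
      gfp = activity * od * lognormal_factor(length(tt), noise_cv))
    list(induced = mk(act), uninduced = mk(basal * rep(1, length(tt))),
         truth = list(fold = fold, onset_hr = onset_hr, basal = basal))
  })
}
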