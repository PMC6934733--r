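# Forward simulator of sensor-expressing tissue under the three-channel
# acquisition model; the ground-truth source for every acceptance test.
#
# World model: a Voronoi cell mosaic; per-cell sensor expression E
# (lognormal, emulating transgene dosage variation), per-cell metabolite
# concentration c, bound fraction f = c/(c+Kd), FRET efficiency
# eps = (1-f)*eps_unbound + f*eps_bound. Autofluorescence is a smoothed
# lognormal amplitude field (spatially structured, unit mean, CV
# `af_heterogeneity`) scaled by `af_mean`, plus sparse bright granules.
# Photon emission is Poisson; detection adds Gaussian read noise.

.default_signatures <- function() {
  list(donor = spectral_signature("donor_fluor", c(0.80, 0.20, 0.00)),
       acceptor = spectral_signature("acceptor_fluor", c(0.05, 0.90, 0.05)),
       autofluo = spectral_signature("autofluorescence", c(0.30, 0.20, 0.50)))
}

#' Simulation configuration
#'
#' Defaults describe a mid-size larval-tissue field of view in the regime
#' the three-channel design addresses: autofluorescence flux of the same
#' order as the sensor flux (af_mean 500 vs photon budget 500 at E = 1),
#' strong spatial AF heterogeneity (CV 0.5) with sparse bright granules,
#' and Poisson-limited detection with mild read noise.
#'
#' @param height,width image size in pixels.
#' @param n_cells number of Voronoi cells.
#' @param expression_meanlog,expression_sdlog lognormal parameters of
#'   per-cell sensor expression E.
#' @param conc named list describing the per-cell concentration
#'   distribution: `list(dist = "uniform", min, max)`,
#'   `list(dist = "lognormal", meanlog, sdlog)` or
#'   `list(dist = "fixed", value)`; units mM. Default uniform on
#'   \[0, 10\] mM, the physiological range of these metabolites.
#' @param sensor a [sensor_spec()].
#' @param signatures list with `donor`, `acceptor`, `autofluo`
#'   [spectral_signature()]s.
#' @param af_mean mean autofluorescence amplitude (photon counts / pixel).
#' @param af_heterogeneity coefficient of variation of the AF field.
#' @param af_granule_density fraction of pixels carrying a bright granule
#'   (amplitude 5 x af_mean, added).
#' @param af_smooth_sigma Gaussian smoothing length (px) of the AF field.
#' @param photon_budget expected sensor photons per pixel at E = 1.
#' @param read_noise_sd detector read noise SD (counts).
#' @param gamma relative acceptor/donor detection efficiency (instrument
#'   specific; 1 by default).
#' @param direct_excitation fraction of the photon budget emitted by the
#'   acceptor through direct excitation at the donor wavelength (0 for an
#'   ideal setup).
#' @param seed integer RNG seed; identical config + seed give bitwise
#'   identical output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(height = 128, width = 128, n_cells = 100,
                              expression_meanlog = 0, expression_sdlog = 0.3,
                              conc = list(dist = "uniform", min = 0, max = 10),
                              sensor = sensor_spec(),
                              signatures = .default_signatures(),
                              af_mean = 500, af_heterogeneity = 0.5,
                              af_granule_density = 0.01, af_smooth_sigma = 4,
                              photon_budget = 500, read_noise_sd = 2,
                              gamma = 1, direct_excitation = 0, seed = 1L) {
  stopifnot(height >= 1, width >= 1, n_cells >= 1,
            af_mean >= 0, af_heterogeneity >= 0,
            af_granule_density >= 0, af_granule_density <= 1,
            photon_budget > 0, read_noise_sd >= 0, gamma > 0,
            direct_excitation >= 0)
  if (n_cells > height * width) stop("n_cells exceeds pixel count")
  stopifnot(inherits(sensor, "sensor_spec"))
  for (nm in c("donor", "acceptor", "autofluo"))
    if (!inherits(signatures[[nm]], "spectral_signature"))
      stop("signatures$", nm, " must be a spectral_signature")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog, conc = conc,
                 sensor = sensor, signatures = signatures, af_mean = af_mean,
                 af_heterogeneity = af_heterogeneity,
                 af_granule_density = af_granule_density,
                 af_smooth_sigma = af_smooth_sigma,
                 photon_budget = photon_budget,
                 read_noise_sd = read_noise_sd, gamma = gamma,
                 direct_excitation = direct_excitation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.draw_conc <- function(conc, n) {
  switch(conc$dist,
         uniform = stats::runif(n, conc$min, conc$max),
         lognormal = stats::rlnorm(n, conc$meanlog, conc$sdlog),
         fixed = rep(conc$value, n),
         stop("unknown concentration distribution: ", conc$dist))
}

# separable Gaussian blur with circular boundary (keeps the mean exactly)
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(mm) {
    padded <- rbind(mm[(nrow(mm) - half + 1):nrow(mm), , drop = FALSE], mm,
                    mm[1:half, , drop = FALSE])
    out <- apply(padded, 2, function(col)
      stats::filter(col, k, sides = 2)[(half + 1):(half + nrow(mm))])
    matrix(out, nrow(mm), ncol(mm))
  }
  t(blur1(t(blur1(m))))
}

#' Generate a synthetic tissue ground truth
#'
#' Seeded Voronoi tessellation of `n_cells` uniformly random sites;
#' per-cell expression, concentration, bound fraction and FRET efficiency;
#' spatially structured autofluorescence field. Deterministic under the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return an object of class `tissue_ground_truth` with `cell_labels`
#'   ([label_mask()]), per-cell vectors `expression`, `concentration`,
#'   `bound_fraction`, `fret_eff`, per-pixel `af_field` and
#'   `bleach_factor`, and the site coordinates.
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  h <- config$height; w <- config$width; k <- config$n_cells
  site_r <- stats::runif(k, 0.5, h + 0.5)
  site_c <- stats::runif(k, 0.5, w + 0.5)
  pr <- rep(seq_len(h), times = w)
  pc <- rep(seq_len(w), each = h)
  # nearest site per pixel; ties broken by lowest cell index
  d2 <- outer(pr, site_r, function(a, b) (a - b)^2) +
        outer(pc, site_c, function(a, b) (a - b)^2)
  labels <- matrix(max.col(-d2, ties.method = "first"), h, w)
  expression <- stats::rlnorm(k, config$expression_meanlog,
                              config$expression_sdlog)
  concentration <- .draw_conc(config$conc, k)
  f <- fraction_bound(concentration, config$sensor$kd)
  eps <- (1 - f) * config$sensor$fret_eff_unbound +
         f * config$sensor$fret_eff_bound
  cv <- config$af_heterogeneity
  af <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    base <- matrix(stats::rlnorm(h * w, -sdlog^2 / 2, sdlog), h, w)
    sm <- .gauss_blur(base, config$af_smooth_sigma)
    s <- stats::sd(as.vector(sm))
    if (s > 0) sm <- 1 + (sm - mean(sm)) / s * cv   # restore target CV
    pmax(sm, 0)
  } else matrix(1, h, w)
  af <- af * config$af_mean
  n_gran <- round(config$af_granule_density * h * w)
  if (n_gran > 0) {
    pos <- sample.int(h * w, n_gran)
    af[pos] <- af[pos] + 5 * config$af_mean
  }
  structure(list(cell_labels = label_mask(labels), expression = expression,
                 concentration = concentration, bound_fraction = f,
                 fret_eff = eps, af_field = af,
                 bleach_factor = matrix(1, h, w),
                 site_row = site_r, site_col = site_c,
                 config_seed = config$seed),
            class = "tissue_ground_truth")
}

#' Render an acquisition from a ground truth (forward model)
#'
#' Per pixel in cell k: expected donor photons
#' `photon_budget * E_k * (1 - eps_eff)` and expected sensitized acceptor
#' photons `photon_budget * E_k * eps_eff * gamma`, where
#' `eps_eff = eps_k * bleach_factor(pixel)`; direct acceptor excitation
#' adds `photon_budget * E_k * direct_excitation * gamma`. Each species'
#' photons are spread over the three channels by its signature and the AF
#' field adds its own contribution. With `noise = TRUE`, channel counts are
#' Poisson sampled and Gaussian read noise is added (clamped at 0).
#'
#' @param truth a [generate_tissue()] result.
#' @param config the matching [simulation_config()].
#' @param noise logical; FALSE returns the noiseless expectation.
#' @param specimen `"sensor"` (default), `"donor_only"` (donor fluorophore
#'   only, no FRET), `"acceptor_only"` (acceptor only: direct excitation
#'   signal only) or `"sensor_free"` (autofluorescence only).
#' @param seed RNG seed for the noise draw; defaults to `config$seed + 1`
#'   so truth generation and rendering are decoupled but jointly
#'   reproducible.
#' @return an [acquisition_set()].
#' @export
render_acquisition <- function(truth, config, noise = TRUE,
                               specimen = c("sensor", "donor_only",
                                            "acceptor_only", "sensor_free"),
                               seed = config$seed + 1L) {
  stopifnot(inherits(truth, "tissue_ground_truth"),
            inherits(config, "simulation_config"))
  specimen <- match.arg(specimen)
  h <- config$height; w <- config$width
  lab <- truth$cell_labels$labels
  E <- truth$expression[lab]
  eps_eff <- truth$fret_eff[lab] * truth$bleach_factor
  B <- config$photon_budget
  d_mean <- switch(specimen,
                   sensor = B * E * (1 - eps_eff),
                   donor_only = B * E,
                   matrix(0, h, w))
  a_mean <- switch(specimen,
                   sensor = B * E * eps_eff * config$gamma +
                            B * E * config$direct_excitation * config$gamma,
                   acceptor_only = B * E * config$direct_excitation *
                                   config$gamma,
                   matrix(0, h, w))
  sig_d <- config$signatures$donor$coefficients
  sig_a <- config$signatures$acceptor$coefficients
  sig_af <- config$signatures$autofluo$coefficients
  dim(d_mean) <- dim(a_mean) <- c(h, w)
  chan_mean <- lapply(1:3, function(ch)
    d_mean * sig_d[ch] + a_mean * sig_a[ch] + truth$af_field * sig_af[ch])
  if (noise) {
    set.seed(seed)
    chan <- lapply(chan_mean, function(m) {
      v <- stats::rpois(h * w, as.vector(m)) +
           stats::rnorm(h * w, 0, config$read_noise_sd)
      matrix(pmax(v, 0), h, w)
    })
  } else chan <- chan_mean
  acquisition_set(
    channel_image(chan[[1]], "donor"),
    channel_image(chan[[2]], "acceptor"),
    channel_image(chan[[3]], "autofluo"),
    sample_id = sprintf("synthetic_%s_seed%d", specimen, seed))
}

#' Apply acceptor photobleaching to a ground truth
#'
#' Inside the mask the effective FRET efficiency becomes `eps * (1 - b)`
#' (surviving acceptors keep transferring; sensitized emission scales by
#' `1 - b`); outside the mask nothing changes.
#'
#' @param truth a [generate_tissue()] result.
#' @param bleach_mask a [label_mask()] within the image.
#' @param bleach_fraction b in \[0, 1\].
#' @return a modified `tissue_ground_truth`.
#' @export
simulate_bleach <- function(truth, bleach_mask, bleach_fraction) {
  stopifnot(inherits(truth, "tissue_ground_truth"),
            inherits(bleach_mask, "label_mask"))
  if (bleach_fraction < 0 || bleach_fraction > 1)
    stop("bleach_fraction must be in [0, 1]")
  if (!all(dim(bleach_mask$labels) == dim(truth$bleach_factor)))
    stop("bleach mask dimensions do not match the tissue")
  out <- truth
  out$bleach_factor[bleach_mask$labels > 0] <-
    out$bleach_factor[bleach_mask$labels > 0] * (1 - bleach_fraction)
  out
}

#' Two-half expression-gradient scenario (1x vs 2x transgene dosage)
#'
#' Builds the fixture for the expression-independence test: a tissue whose
#' left-half cells express at E0 and right-half cells at exactly 2 * E0
#' (constant within each half, emulating 1 and 2 transgene copies), with an
#' identical concentration distribution in both halves and heterogeneous
#' autofluorescence. The truth gains a per-cell `half` assignment (1 =
#' left/E0, 2 = right/2 E0) decided by each cell's Voronoi site column.
#'
#' @param config a [simulation_config()].
#' @param noise passed to [render_acquisition()].
#' @return list with `truth` and `acquisition`.
#' @export
scenario_expression_gradient <- function(config, noise = TRUE) {
  truth <- generate_tissue(config)
  e0 <- exp(config$expression_meanlog)
  half <- ifelse(truth$site_col <= config$width / 2, 1L, 2L)
  truth$expression <- ifelse(half == 1L, e0, 2 * e0)
  truth$half <- half
  list(truth = truth, acquisition = render_acquisition(truth, config,
                                                       noise = noise))
}
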