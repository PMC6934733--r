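# Sensor biophysics and validation analyses.
#
# The sensors (Laconic, Pyronic, OGsor family) are intramolecular CFP/YFP
# FRET reporters: metabolite binding elicits a conformational change that
# separates donor from acceptor, so FRET efficiency and the acceptor/donor
# ratio DECREASE with metabolite concentration. Binding is modeled as
# single-site equilibrium, f = c / (c + Kd).

#' FRET sensor specification
#'
#' Holds the binding and photophysical parameters of one sensor. No
#' published calibration constants exist for these sensors, so the defaults
#' are placeholders (flagged `calibrated = FALSE`) meant for simulation and
#' testing, not for interpreting real data.
#'
#' @param name,metabolite free text.
#' @param kd dissociation constant (mM), > 0.
#' @param ratio_unbound,ratio_bound dimensionless FRET ratios of the
#'   unbound (high-FRET, r_max) and bound (low-FRET, r_min) states;
#'   `ratio_bound < ratio_unbound`.
#' @param fret_eff_unbound,fret_eff_bound FRET efficiencies of the two
#'   states, in \[0, 1\], with `fret_eff_bound < fret_eff_unbound`.
#' @param calibrated logical flag; FALSE marks placeholder values.
#' @return an object of class `sensor_spec`.
#' @export
sensor_spec <- function(name = "Laconic", metabolite = "lactate", kd = 5,
                        ratio_unbound = 1.0, ratio_bound = 0.4,
                        fret_eff_unbound = 0.35, fret_eff_bound = 0.10,
                        calibrated = FALSE) {
  if (kd <= 0) stop("kd must be > 0")
  if (ratio_bound >= ratio_unbound)
    stop("ratio_bound must be < ratio_unbound (binding reduces FRET)")
  if (fret_eff_bound >= fret_eff_unbound)
    stop("fret_eff_bound must be < fret_eff_unbound (binding reduces FRET)")
  if (fret_eff_unbound > 1 || fret_eff_bound < 0)
    stop("FRET efficiencies must lie in [0, 1]")
  structure(list(name = name, metabolite = metabolite, kd = kd,
                 ratio_unbound = ratio_unbound, ratio_bound = ratio_bound,
                 fret_eff_unbound = fret_eff_unbound,
                 fret_eff_bound = fret_eff_bound, calibrated = calibrated),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec> %s (%s), Kd = %g mM%s\n", x$name, x$metabolite,
              x$kd, if (!x$calibrated) " [uncalibrated placeholders]" else ""))
  cat(sprintf("  ratio %g -> %g, FRET eff %g -> %g (unbound -> bound)\n",
              x$ratio_unbound, x$ratio_bound, x$fret_eff_unbound,
              x$fret_eff_bound))
  invisible(x)
}

#' Equilibrium bound fraction
#'
#' Single-site binding: f = c / (c + Kd).
#'
#' @param c metabolite concentration (mM), >= 0 (vectorized).
#' @param kd dissociation constant (mM), > 0.
#' @return bound fraction in \[0, 1\].
#' @export
fraction_bound <- function(c, kd) {
  if (kd <= 0) stop("kd must be > 0")
  if (any(c < 0)) stop("concentration must be >= 0")
  c / (c + kd)
}

#' Predicted FRET ratio at a given concentration
#'
#' r(c) = r_max - (r_max - r_min) * f(c); strictly decreasing in c, from
#' `ratio_unbound` at c = 0 to `ratio_bound` at saturation.
#'
#' @param c concentration (mM), vectorized.
#' @param spec a [sensor_spec()].
#' @return predicted dimensionless ratio.
#' @export
predicted_ratio <- function(c, spec) {
  stopifnot(inherits(spec, "sensor_spec"))
  spec$ratio_unbound - (spec$ratio_unbound - spec$ratio_bound) *
    fraction_bound(c, spec$kd)
}

#' Fit a dose-response (titration) curve
#'
#' Nonlinear least squares of mean per-organ FRET ratios against the
#' single-site model r(c) = r_max - (r_max - r_min) * c / (c + kd).
#' Deterministic given the starting values; the default start takes r_max
#' and r_min from the extreme observed ratios and kd from the concentration
#' nearest half-response.
#'
#' @param concs concentrations (mM), >= 4 points, >= 3 distinct values.
#' @param ratios observed mean ratios, same length.
#' @param init optional named list/vector with starting `kd`, `r_max`,
#'   `r_min`.
#' @return an object of class `dose_response_fit` with `kd_hat`, `r_max_hat`,
#'   `r_min_hat`, `rss`, `n_points`, and `kd_at_bound` flag.
#' @export
fit_dose_response <- function(concs, ratios, init = NULL) {
  if (length(concs) != length(ratios)) stop("concs and ratios lengths differ")
  if (length(concs) < 4L) stop("need at least 4 titration points")
  if (length(unique(concs)) < 3L) stop("need at least 3 distinct concentrations")
  if (any(concs < 0)) stop("concentrations must be >= 0")
  span <- diff(range(ratios))
  if (span <= .Machine$double.eps^0.5 * max(abs(ratios), 1))
    stop("ratios show no response; kd is unidentifiable")
  if (is.null(init)) {
    o <- order(concs)
    r_max0 <- max(ratios); r_min0 <- min(ratios)
    half <- (r_max0 + r_min0) / 2
    kd0 <- concs[o][which.min(abs(ratios[o] - half))]
    if (kd0 <= 0) kd0 <- stats::median(concs[concs > 0])
    init <- list(kd = kd0, r_max = r_max0, r_min = r_min0)
  }
  df <- data.frame(c = concs, r = ratios)
  lo <- c(kd = 1e-6, r_max = -Inf, r_min = -Inf)
  hi <- c(kd = 1e6, r_max = Inf, r_min = Inf)
  fit <- stats::nls(r ~ r_max - (r_max - r_min) * c / (c + kd), data = df,
                    start = init[c("kd", "r_max", "r_min")],
                    algorithm = "port", lower = lo, upper = hi,
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = FALSE))
  est <- stats::coef(fit)
  at_bound <- est[["kd"]] <= lo[["kd"]] * 1.01 || est[["kd"]] >= hi[["kd"]] * 0.99
  if (at_bound) warning("kd_hat is at the optimization bound; ",
                        "treat it as unidentifiable")
  structure(list(kd_hat = est[["kd"]], r_max_hat = est[["r_max"]],
                 r_min_hat = est[["r_min"]],
                 rss = sum(stats::resid(fit)^2),
                 n_points = length(concs), kd_at_bound = at_bound),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> kd = %.4g mM, r_max = %.4g, ",
                     "r_min = %.4g (rss %.3g, n = %d)%s\n"),
              x$kd_hat, x$r_max_hat, x$r_min_hat, x$rss, x$n_points,
              if (x$kd_at_bound) " [kd at bound]" else ""))
  invisible(x)
}

.mask_mean <- function(img, mask) {
  sel <- mask$labels > 0
  if (!any(sel)) stop("empty mask")
  mean(img[sel])
}

#' Acceptor-photobleaching analysis (donor de-quenching)
#'
#' If FRET occurs, destroying the acceptor in a region must increase donor
#' emission there (the donor is de-quenched), while an unbleached control
#' region stays put. Both acquisitions are unmixed with `M` and mean donor
#' abundances compared per region. For bleach fraction b and FRET efficiency
#' eps the expected donor post/pre factor is (1 - eps*(1-b)) / (1 - eps).
#'
#' @param pre,post co-registered acquisitions before/after bleaching.
#' @param bleach_mask,control_mask disjoint [label_mask()]s.
#' @param M a [build_mixing_matrix()] result.
#' @param min_rel_increase smallest relative donor increase accepted as
#'   FRET confirmation (default 0.05); the control region must stay within
#'   +/- half of it.
#' @param nonneg unmixing policy, see [unmix_image()].
#' @return an object of class `photobleach_result`.
#' @export
analyze_photobleach <- function(pre, post, bleach_mask, control_mask, M,
                                min_rel_increase = 0.05, nonneg = "nnls") {
  stopifnot(inherits(bleach_mask, "label_mask"),
            inherits(control_mask, "label_mask"))
  if (any(bleach_mask$labels > 0 & control_mask$labels > 0))
    stop("bleach and control masks must be disjoint")
  u_pre <- unmix_image(pre, M, nonneg)
  u_post <- unmix_image(post, M, nonneg)
  donor_pre <- .mask_mean(u_pre$donor_abundance, bleach_mask)
  donor_post <- .mask_mean(u_post$donor_abundance, bleach_mask)
  donor_pre_ctrl <- .mask_mean(u_pre$donor_abundance, control_mask)
  donor_post_ctrl <- .mask_mean(u_post$donor_abundance, control_mask)
  if (donor_pre <= 0) stop("mean donor abundance is zero in the bleach region")
  rel <- donor_post / donor_pre - 1
  ctrl_rel <- if (donor_pre_ctrl > 0) donor_post_ctrl / donor_pre_ctrl - 1
              else NA_real_
  confirmed <- is.finite(ctrl_rel) && rel >= min_rel_increase &&
    abs(ctrl_rel) <= min_rel_increase / 2
  structure(list(donor_pre = donor_pre, donor_post = donor_post,
                 donor_pre_ctrl = donor_pre_ctrl,
                 donor_post_ctrl = donor_post_ctrl,
                 relative_donor_increase = rel,
                 control_relative_change = ctrl_rel,
                 fret_confirmed = confirmed),
            class = "photobleach_result")
}

#' @export
print.photobleach_result <- function(x, ...) {
  cat(sprintf(paste0("<photobleach_result> donor %+.2f%% in bleach region ",
                     "(control %+.2f%%): FRET %s\n"),
              100 * x$relative_donor_increase,
              100 * x$control_relative_change,
              if (x$fret_confirmed) "confirmed" else "not confirmed"))
  invisible(x)
}

#' Direct acceptor-excitation control
#'
#' A core FRET assumption is that the donor excitation wavelength does not
#' excite the acceptor directly, so acceptor-channel emission from an
#' acceptor-only specimen (e.g. a YFP-only line) must be negligible against
#' a sensor-expressing reference acquired the same way. Autofluorescence is
#' subtracted channel-wise from the amplitude inferred from the 600 nm
#' channel when `af_sig` is given.
#'
#' @param acceptor_only acquisition of the acceptor-only specimen, excited
#'   at the donor wavelength.
#' @param reference acquisition of a sensor-expressing specimen providing
#'   the comparison scale.
#' @param threshold passing bound on the median signal ratio (default 0.05).
#' @param af_sig optional autofluorescence [spectral_signature()] for AF
#'   subtraction.
#' @return logical: TRUE if the control passes (no meaningful direct
#'   excitation), with attributes `signal_fraction`.
#' @export
check_direct_excitation <- function(acceptor_only, reference,
                                    threshold = 0.05, af_sig = NULL) {
  if (missing(reference) || is.null(reference))
    stop("a donor-expressing reference acquisition is required for scale")
  med_acc <- function(acq) {
    y_acc <- acq$acceptor$pixels
    if (!is.null(af_sig)) {
      amp <- acq$autofluo$pixels / af_sig$coefficients[3]
      y_acc <- y_acc - amp * af_sig$coefficients[2]
    }
    stats::median(y_acc)
  }
  s_only <- med_acc(acceptor_only)
  s_ref <- med_acc(reference)
  if (s_ref <= 0) stop("reference acceptor-channel median is <= 0")
  frac <- max(s_only, 0) / s_ref
  structure(frac <= threshold, signal_fraction = frac, threshold = threshold)
}

#' Donor/acceptor anti-correlation across cells
#'
#' Genuine FRET-state variation moves donor and acceptor emission in
#' opposite directions. Each cell's donor and acceptor abundances are
#' normalized by their sum (removing expression differences) and the Pearson
#' correlation of the two fractions across cells is returned. Note that the
#' two normalized fractions are exact complements, so any genuine variation
#' yields r = -1; the informative failure mode is the zero-variance error
#' raised when cells differ only in expression (no FRET-state variation).
#'
#' @param cell_means data.frame with columns `donor` and `acceptor`
#'   (per-cell mean abundances), >= 5 cells.
#' @return Pearson correlation coefficient.
#' @export
spectral_anticorrelation <- function(cell_means) {
  if (!all(c("donor", "acceptor") %in% names(cell_means)))
    stop("cell_means must have 'donor' and 'acceptor' columns")
  if (nrow(cell_means) < 5L) stop("need at least 5 cells")
  tot <- cell_means$donor + cell_means$acceptor
  if (any(tot <= 0)) stop("cells with non-positive total abundance")
  d <- cell_means$donor / tot
  a <- cell_means$acceptor / tot
  if (stats::sd(d) == 0 || stats::sd(a) == 0)
    stop("zero variance in normalized fractions: no FRET-state variation ",
         "across cells (expression-only differences are removed by the ",
         "normalization)")
  stats::cor(d, a)
}
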