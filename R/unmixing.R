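# Per-pixel three-species spectral linear unmixing.
#
# Model: each pixel's three channel intensities are a non-negative linear
# combination of three spectral species (donor fluorophore, acceptor
# fluorophore, autofluorescence), each described by a unit-sum emission
# signature over the (donor, acceptor, autofluo) windows. The autofluorescence
# spectral *shape* is assumed spatially uniform; only its amplitude varies per
# pixel - this is the key assumption that makes a single extra 600 nm channel
# sufficient to remove heterogeneous tissue autofluorescence.

.species_names <- c("donor_fluor", "acceptor_fluor", "autofluorescence")

#' Spectral emission signature of one species
#'
#' Three non-negative relative emission weights, one per acquisition channel
#' (donor window, acceptor window, autofluorescence window), normalized to
#' sum to 1.
#'
#' @param species `"donor_fluor"`, `"acceptor_fluor"` or `"autofluorescence"`.
#' @param coefficients numeric length-3 vector of non-negative weights; it is
#'   normalized to unit sum.
#' @return an object of class `spectral_signature`.
#' @export
spectral_signature <- function(species, coefficients) {
  species <- match.arg(species, .species_names)
  if (length(coefficients) != 3L || anyNA(coefficients))
    stop("coefficients must be 3 finite numbers")
  if (any(coefficients < 0)) stop("coefficients must be >= 0")
  s <- sum(coefficients)
  if (s <= 0) stop("coefficients must not all be zero")
  structure(list(species = species, coefficients = coefficients / s),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature> %s: (%.4f, %.4f, %.4f)\n", x$species,
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  invisible(x)
}

.channel_stack <- function(acq) {
  rbind(as.vector(acq$donor$pixels),
        as.vector(acq$acceptor$pixels),
        as.vector(acq$autofluo$pixels))
}

#' Estimate the autofluorescence signature from sensor-free control tissue
#'
#' Takes the per-channel medians over the masked pixels (medians are robust
#' to the bright autofluorescent granules typical of larval tissue) and
#' normalizes them to unit sum.
#'
#' @param control an [acquisition_set()] from tissue not expressing the
#'   sensor.
#' @param mask a [label_mask()]; all pixels with label > 0 are used
#'   (at least 50 required).
#' @return a `spectral_signature` for `"autofluorescence"`.
#' @export
estimate_af_signature <- function(control, mask) {
  stopifnot(inherits(control, "acquisition_set"), inherits(mask, "label_mask"))
  sel <- as.vector(mask$labels) > 0
  if (sum(sel) < 50L)
    stop("autofluorescence estimation needs >= 50 masked pixels, got ",
         sum(sel))
  y <- .channel_stack(control)[, sel, drop = FALSE]
  med <- apply(y, 1, stats::median)
  if (any(med <= 0))
    stop("a channel median is <= 0 in the control region; cannot normalize")
  spectral_signature("autofluorescence", med)
}

#' Estimate donor and acceptor signatures from single-fluorophore references
#'
#' For each reference acquisition the autofluorescence contribution is
#' inferred per pixel from the 600 nm channel (amplitude = I_AF / af
#' coefficient) and subtracted channel-wise; per-channel medians of the
#' remainder, clamped at zero, normalized to unit sum, give the signature.
#'
#' When the sensor fluorophore itself bleeds into the 600 nm window the
#' sensor + AF decomposition has an exact gauge freedom (no pure-AF pixels
#' can be told apart from faint sensor), and this estimator returns the
#' zero-bleed representative of the gauge class: the signature with a zero
#' autofluo-window coefficient that, together with the AF signature, spans
#' exactly the same model space. Unmixing with the gauge representative
#' rescales the affected abundance by a constant factor and leaves every
#' FRET-ratio comparison intact.
#'
#' @param donor_only acquisition from a specimen expressing only the donor
#'   fluorophore (CFP).
#' @param acceptor_only acquisition from a specimen expressing only the
#'   acceptor fluorophore (YFP), cf. the YFP-only control line.
#' @param af_sig autofluorescence [spectral_signature()].
#' @param masks a single [label_mask()] used for both references, or a list
#'   with elements `donor` and `acceptor`.
#' @return list with elements `donor` and `acceptor` (spectral signatures).
#' @export
estimate_sensor_signatures <- function(donor_only, acceptor_only, af_sig,
                                       masks) {
  stopifnot(inherits(af_sig, "spectral_signature"),
            af_sig$species == "autofluorescence")
  if (inherits(masks, "label_mask")) masks <- list(donor = masks,
                                                   acceptor = masks)
  af <- af_sig$coefficients
  one <- function(acq, mask, species, principal) {
    sel <- as.vector(mask$labels) > 0
    if (!any(sel)) stop("empty reference mask")
    y <- .channel_stack(acq)[, sel, drop = FALSE]
    af_amp <- y[3, ] / af[3]     # AF amplitude read off the autofluo channel
    rem <- y - outer(af, af_amp)
    med <- pmax(apply(rem, 1, stats::median), 0)
    if (med[principal] <= 0)
      stop("reference remainder non-positive in the principal channel")
    spectral_signature(species, med)
  }
  list(donor = one(donor_only, masks$donor, "donor_fluor", 1L),
       acceptor = one(acceptor_only, masks$acceptor, "acceptor_fluor", 2L))
}

#' Stack the three signatures into a mixing matrix
#'
#' Rows are species (donor_fluor, acceptor_fluor, autofluorescence), columns
#' are channels (donor, acceptor, autofluo window). The 2-norm condition
#' number is computed by SVD and the matrix is rejected above `cond_cap`
#' (spectrally indistinguishable species make the per-pixel solve
#' meaningless).
#'
#' @param donor_sig,acceptor_sig,af_sig [spectral_signature()] objects.
#' @param cond_cap largest acceptable condition number (default 1e3).
#' @return an object of class `mixing_matrix` with fields `matrix`
#'   (3x3) and `condition_number`.
#' @export
build_mixing_matrix <- function(donor_sig, acceptor_sig, af_sig,
                                cond_cap = 1e3) {
  sigs <- list(donor_sig, acceptor_sig, af_sig)
  for (i in 1:3) {
    if (!inherits(sigs[[i]], "spectral_signature"))
      stop("all three arguments must be spectral_signature objects")
    if (sigs[[i]]$species != .species_names[i])
      stop("signature ", i, " must be for species ", .species_names[i])
  }
  M <- do.call(rbind, lapply(sigs, `[[`, "coefficients"))
  dimnames(M) <- list(.species_names, c("donor_ch", "acceptor_ch",
                                        "autofluo_ch"))
  d <- svd(M, nu = 0, nv = 0)$d
  cond <- if (min(d) <= 0) Inf else max(d) / min(d)
  if (!is.finite(cond) || cond > cond_cap)
    stop(sprintf(paste0("mixing matrix is singular or ill-conditioned ",
                        "(condition number %.3g > cap %.3g): species are ",
                        "spectrally indistinguishable"), cond, cond_cap))
  structure(list(matrix = M, condition_number = cond),
            class = "mixing_matrix")
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat("<mixing_matrix> condition number", format(x$condition_number), "\n")
  print(round(x$matrix, 4))
  invisible(x)
}

# Vectorized 3-variable NNLS with a shared design matrix.
# Enumerates the 8 support sets in the fixed order (full, pairs, singletons,
# empty) and assigns each pixel the first KKT-satisfying candidate; with a
# full-rank design the optimum is unique, so the order only breaks exact ties
# deterministically (donor, acceptor, AF precedence).
.nnls3 <- function(A, Y, tol = 1e-10) {
  G <- crossprod(A)
  B <- crossprod(A, Y)
  n <- ncol(Y)
  X <- matrix(0, 3, n)
  done <- rep(FALSE, n)
  supports <- list(1:3, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1L, 2L, 3L,
                   integer(0))
  scale_ref <- pmax(colSums(abs(B)), 1)
  for (S in supports) {
    if (all(done)) break
    idx <- which(!done)
    cand <- matrix(0, 3, length(idx))
    if (length(S) > 0)
      cand[S, ] <- solve(G[S, S, drop = FALSE], B[S, idx, drop = FALSE])
    grad <- G %*% cand - B[, idx, drop = FALSE]
    tolv <- tol * scale_ref[idx]
    feas <- rep(TRUE, length(idx))
    for (j in S) feas <- feas & cand[j, ] >= -tolv
    opt <- feas
    for (j in setdiff(1:3, S)) opt <- opt & grad[j, ] >= -tolv
    if (any(opt)) {
      take <- idx[opt]
      X[, take] <- pmax(cand[, opt, drop = FALSE], 0)
      done[take] <- TRUE
    }
  }
  # numerical safety net: any pixel left unassigned falls back to clamping
  if (!all(done)) {
    idx <- which(!done)
    X[, idx] <- pmax(solve(A, Y[, idx, drop = FALSE]), 0)
  }
  X
}

#' Unmix an acquisition into per-pixel species abundances
#'
#' Solves, per pixel, intensities = t(M) %*% abundances for the three
#' species. With `nonneg = "clamp"` the exactly determined 3x3 system is
#' solved and negative abundances are clamped to zero; with
#' `nonneg = "nnls"` (default) the non-negativity-constrained least-squares
#' solution is used. `residual_norm` is the per-pixel Euclidean norm of the
#' model mismatch of the returned (constrained/clamped) abundances; it is
#' zero on noiseless forward-model images.
#'
#' @param acq an [acquisition_set()].
#' @param M a [build_mixing_matrix()] result.
#' @param nonneg `"nnls"` or `"clamp"`.
#' @return an object of class `unmixed_image` with matrices
#'   `donor_abundance`, `acceptor_abundance`, `autofluo_abundance`,
#'   `residual_norm` and the acquisition's saturation mask.
#' @export
unmix_image <- function(acq, M, nonneg = c("nnls", "clamp")) {
  nonneg <- match.arg(nonneg)
  stopifnot(inherits(acq, "acquisition_set"), inherits(M, "mixing_matrix"))
  A <- t(M$matrix)                      # channels x species
  Y <- .channel_stack(acq)
  X <- if (nonneg == "clamp") pmax(solve(A, Y), 0) else .nnls3(A, Y)
  R <- A %*% X - Y
  dims <- dim(acq$donor$pixels)
  as_img <- function(v) matrix(v, dims[1], dims[2])
  structure(list(donor_abundance = as_img(X[1, ]),
                 acceptor_abundance = as_img(X[2, ]),
                 autofluo_abundance = as_img(X[3, ]),
                 residual_norm = as_img(sqrt(colSums(R^2))),
                 saturation = acq$saturation,
                 nonneg = nonneg),
            class = "unmixed_image")
}

#' Constant-background subtraction (the baseline the unmixing replaces)
#'
#' Subtracts one constant per channel and clamps at zero. This is the
#' classic cell-culture correction; it is only exact when autofluorescence
#' is spatially uniform. The result is marked `background_corrected`, which
#' makes [compute_fret_map()] treat the donor/acceptor channels directly as
#' abundances.
#'
#' @param acq an [acquisition_set()].
#' @param background numeric length-3 vector of per-channel constants
#'   (donor, acceptor, autofluo), all >= 0.
#' @return a background-corrected [acquisition_set()].
#' @export
constant_background_subtract <- function(acq, background) {
  stopifnot(inherits(acq, "acquisition_set"), length(background) == 3L)
  if (any(background < 0)) stop("background constants must be >= 0")
  sub_chan <- function(ch, b) {
    ch$pixels <- pmax(ch$pixels - b, 0)
    ch
  }
  acquisition_set(sub_chan(acq$donor, background[1]),
                  sub_chan(acq$acceptor, background[2]),
                  sub_chan(acq$autofluo, background[3]),
                  time_index = acq$time_index, sample_id = acq$sample_id,
                  saturation = acq$saturation, background_corrected = TRUE)
}

#' Build a FRET map from unmixed abundances or a CB-corrected acquisition
#'
#' The per-pixel ratio is acceptor/donor abundance (sensitized-emission
#' ratio) by default; with this sensor family metabolite binding separates
#' the fluorophores, so a *high* ratio corresponds to a *low* metabolite
#' level. Pixels are invalid where donor + acceptor falls below
#' `min_intensity`, where the donor abundance is zero, or where the
#' acquisition saturated.
#'
#' @param source an `unmixed_image` or a background-corrected
#'   [acquisition_set()] (see [constant_background_subtract()]).
#' @param min_intensity validity threshold in counts (> 0). The default, 10,
#'   is 5x the default read-noise standard deviation of 2 counts: below
#'   that the ratio variance explodes.
#' @param orientation `"acceptor_over_donor"` (default) or
#'   `"donor_over_acceptor"`.
#' @return a [fret_map()].
#' @export
compute_fret_map <- function(source, min_intensity = 10,
                             orientation = c("acceptor_over_donor",
                                             "donor_over_acceptor")) {
  orientation <- match.arg(orientation)
  if (min_intensity <= 0) stop("min_intensity must be > 0")
  if (inherits(source, "unmixed_image")) {
    donor <- source$donor_abundance
    acceptor <- source$acceptor_abundance
    sat <- source$saturation
  } else if (inherits(source, "acquisition_set")) {
    if (!source$background_corrected)
      stop(paste("raw acquisitions must be unmixed (or background-",
                 "corrected) before computing a FRET map"))
    donor <- source$donor$pixels
    acceptor <- source$acceptor$pixels
    sat <- source$saturation
  } else stop("source must be an unmixed_image or acquisition_set")
  denom <- if (orientation == "acceptor_over_donor") donor else acceptor
  valid <- (donor + acceptor >= min_intensity) & denom > 0 & !sat
  ratio <- matrix(NA_real_, nrow(donor), ncol(donor))
  ratio[valid] <- if (orientation == "acceptor_over_donor") {
    acceptor[valid] / donor[valid]
  } else donor[valid] / acceptor[valid]
  fret_map(ratio, valid, min_intensity)
}
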