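# Shared fixtures: all synthetic, built in code at test time.

default_sigs <- function() {
  list(donor = spectral_signature("donor_fluor", c(0.80, 0.20, 0.00)),
       acceptor = spectral_signature("acceptor_fluor", c(0.05, 0.90, 0.05)),
       autofluo = spectral_signature("autofluorescence", c(0.30, 0.20, 0.50)))
}

default_M <- function(sigs = default_sigs()) {
  build_mixing_matrix(sigs$donor, sigs$acceptor, sigs$autofluo)
}

# acquisition with constant per-channel values
const_acq <- function(d, a, af, h = 8, w = 8, ...) {
  acquisition_set(channel_image(matrix(d, h, w), "donor"),
                  channel_image(matrix(a, h, w), "acceptor"),
                  channel_image(matrix(af, h, w), "autofluo"), ...)
}

full_mask <- function(h, w) label_mask(matrix(1L, h, w))

# small, fast simulation world for module tests
tiny_config <- function(...) {
  args <- list(height = 48, width = 48, n_cells = 12, seed = 101L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

# build an acquisition directly from per-pixel species abundances (noiseless
# forward model), independent of render_acquisition
acq_from_abundances <- function(d, a, af, M) {
  A <- t(M$matrix)
  h <- nrow(d); w <- ncol(d)
  Y <- A %*% rbind(as.vector(d), as.vector(a), as.vector(af))
  acquisition_set(channel_image(matrix(Y[1, ], h, w), "donor"),
                  channel_image(matrix(Y[2, ], h, w), "acceptor"),
                  channel_image(matrix(Y[3, ], h, w), "autofluo"))
}
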