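# Shared phantom builders for the test suite (kept small for speed).

tiny_dataset <- function(n_px = 3, mz = c(900, 900.1, 900.2),
                         seed = 1) {
  with_seed <- msidiscrim:::with_seed
  with_seed(seed, {
    ints <- matrix(abs(stats::rnorm(n_px * length(mz), 10, 2)),
                   n_px, length(mz))
    spectra_dataset(mz_axis = mz, intensities = ints,
                    coords = data.frame(x = seq_len(n_px) - 1L, y = 0L),
                    mass_range = c(800, 4000))
  })
}

quick_table <- function(n_components = 20, n_side = 16, d_range = c(1.2, 2),
                        frac = 0.25, seed = 1, cancer_fraction = 0.5) {
  map <- make_phantom(c(n_side, n_side), cancer_fraction, seed)
  lib <- make_component_library(n_components, c(800, 800 + 12 * n_components),
                                frac_discriminatory = frac,
                                effect_size_range = d_range,
                                skew_fraction = 0, seed = seed + 1)
  syn <- synthesize_feature_table(map, lib, seed = seed + 2)
  list(map = map, lib = lib, table = syn$table, roi = syn$roi,
       abundances = syn$abundances)
}

# full two-sided Mann-Whitney p by enumeration of all arrangements
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
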