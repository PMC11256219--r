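# Shared fixtures: small stacks and reduced-size problems built in code.

# A smooth three-interface stack whose roughnesses are well below a third of
# every adjacent thickness (Nevot-Croce validity regime).
smooth_stack <- function(sigma = 2) {
  slab_stack(c(0, 40, 60, 0), c(2.07, 4.0, 1.0, 6.36), c(sigma, sigma, sigma, 0))
}

default_q <- function(n = 150) exp(seq(log(0.009), log(0.3), length.out = n))

# Reduced instrument for fast fitting tests: fewer Q bins, same physics.
fast_instrument <- function(n_bins = 80) instrument_spec("INTER", n_bins = n_bins)

# Simulate the six-dataset joint problem (2 bare + 4 membrane contrasts)
# from a given truth.
simulate_joint <- function(under, membrane, instrument, seed,
                           condition = "Ca", counting_scale = 1,
                           engine = "microslice") {
  contrasts_m <- c("D2O", "AuMW", "PrMW", "H2O")
  dplyr::bind_rows(c(
    lapply(seq_along(c("D2O", "H2O")), function(i) {
      simulate_dataset(under, NULL, c("D2O", "H2O")[i], instrument,
                       seed = seed + i, counting_scale = counting_scale,
                       engine = engine)
    }),
    lapply(seq_along(contrasts_m), function(i) {
      simulate_dataset(under, membrane, contrasts_m[i], instrument,
                       seed = seed + 10 + i, condition = condition,
                       counting_scale = counting_scale, engine = engine)
    })
  ))
}
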