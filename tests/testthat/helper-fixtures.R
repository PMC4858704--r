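# Shared fixtures for the test suite. All synthetic inputs are built in code
# with explicit seeds.

default_geometry <- function() chamber_geometry(2.75, 75, 100)

# WVP values measured for films of increasing beta-sheet content
# (g m^-1 s^-1 Pa^-1), used as arithmetic fixtures.
wvp_fixture <- c(`36` = 7.93e-9, `48` = 5.37e-10, `58` = 6.49e-11)

# noiseless oxygen replicate triple plus stopper for a given film diffusivity
oxygen_fixture <- function(D_cm2_s, D_B = 0.02, noise_rel = 0, seed = 1,
                           geometry = default_geometry()) {
  reps <- lapply(1:3, function(k) {
    gen_oxygen_experiment(D_cm2_s, D_B, geometry, noise_rel = noise_rel,
                          seed = seed * 100 + k,
                          replicate_id = paste0("rep", k))
  })
  stopper <- gen_stopper_experiment(D_B, geometry, noise_rel = noise_rel,
                                    seed = seed * 100 + 99)
  list(reps = reps, stopper = stopper)
}
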