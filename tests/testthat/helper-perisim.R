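# Shared fixtures: deterministic / low-noise response parameters and
# uniform-field observers built in code.

# step-function responder: seen iff stimulus <= threshold, no errors
det_params <- function()
  response_params(fp = 0, fn = 0, fl = 0, sigma_min = 0, sigma_max = 0)

# fixed 1 dB psychometric spread, no response errors
sigma1_params <- function(fl = 0)
  response_params(fp = 0, fn = 0, fl = fl, sigma_min = 1, sigma_max = 1)

# observer with a spatially uniform true field
uniform_observer <- function(S, grid = build_grid("SPARK66"),
                             params = det_params(), age = 50) {
  fld <- perisim:::new_true_field(grid, rep(S, nrow(grid$points)))
  perisim:::new_observer("unif", "normal", age, fld, params)
}

noisy_normal_observer <- function(seed, grid = build_grid("30-2"),
                                  age = 50, params = sigma1_params()) {
  perisim:::new_observer(paste0("n", seed), "normal", age,
                         normal_field(grid, age = age, seed = seed), params)
}

# small training bank of noiseless normal fields for regression tests
training_bank <- function(n = 60, seed = 42, noise_sd = 1) {
  grid <- build_grid("SPARK66")
  t(vapply(seq_len(n), function(i)
    normal_field(grid, age = 40 + (i %% 30), seed = seed + i,
                 sector_sd = 0.5, noise_sd = noise_sd)$sensitivity,
    numeric(66)))
}
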