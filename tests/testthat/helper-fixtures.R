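# Shared fixtures, built in code at test time.

small_wedge <- function(n_vertices = 400, ratio = 2) {
  make_cortical_ribbon("wedge", n_vertices = n_vertices, thickness = 2,
                       ratio = ratio)
}

quick_bold <- function(mesh = small_wedge(), truth = laminar_truth(),
                       noise_sd = 0, seed = 1, spacing = 0.4, ...) {
  ev <- make_block_design(3, 18, 12, seed = seed)
  simulate_bold_run(mesh, truth, ev, noise_sd = noise_sd, seed = seed,
                    spacing = spacing, ...)
}

# low-spatial-frequency half of the condition grid (6 conditions), keeps
# EEG simulations small while exercising both tag assignments
low_sf_conditions <- function() {
  cc <- enumerate_conditions()
  cc[cc$sf == "low", ]
}

quick_eeg <- function(truth = ssvep_truth(noise_sd = 0), n_trials = 2,
                      seed = 1, conditions = low_sf_conditions(), ...) {
  simulate_ssvep_recording(truth, n_trials = n_trials, seed = seed,
                           conditions = conditions, ...)
}

# von Mises sampler (Best & Fisher 1979), independent of the package
rvm <- function(n, mu = 0, kappa = 1) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  atan2(sin(out), cos(out))
}
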