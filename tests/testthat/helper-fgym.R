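# Shared fixtures for the suite. The registry loader caches, so repeated
# calls are cheap.
reg <- fgym::load_registry()

# Noise-free generator configurations used by the recovery tests: drivers
# kept away from the 5-cm calliper limit so every record lies exactly on the
# generating model surface.
recovery_plots <- function(seed, variant, n = 200,
                           noise = list(th = 0, bas = 0, vol = 0), ...) {
  generate_plots(n, seed = seed, variant = variant,
                 age_mean = 120, age_sd = 35, age_range = c(80, 195),
                 sci_mean = 15, sci_sd = 2.2, sci_range = c(12, 19.7),
                 noise = noise, ...)
}

max_rel_err <- function(estimates, truth) {
  truth <- unlist(truth)
  est <- unlist(estimates[names(truth)])
  max(abs(est - truth) / abs(truth))
}

# A tiny hand-built assortment table: two rows, valid proportions.
toy_assortment_table <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "dbh_midpoint_cm,p_large,p_middle,p_small,p_short,p_fuel,p_bark",
    "10,0,0,0.8,0,0.1,0.1",
    "30,0.3,0.4,0.1,0,0.1,0.1"), path)
  read_assortment_table(path)
}

published_reference <- function() {
  read.csv(system.file("extdata", "published_simulations_age80.csv",
                       package = "fgym"))
}
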