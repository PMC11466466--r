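# Cached phantom cases shared across test files (built once per test run).

.case_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .case_cache)) assign(key, force(expr), envir = .case_cache)
  get(key, envir = .case_cache)
}

# small, fast phantom for unit tests (64^3)
small_params <- function(...) phantom_params(size = c(64, 64, 64), ...)

small_case <- function() cached("small_case", generate_case(small_params(), seed = 42, compute_dose = FALSE))

small_case_dose <- function() cached("small_case_dose", generate_case(small_params(), seed = 42, compute_dose = TRUE))

# identity fraction: no anatomy change, no setup error, no degradation
identity_params <- function(...)
  small_params(bladder_scale = 1, rectum_scale = 1, deform_mm = 0,
               rigid_mm = 0, rigid_deg = 0, target_shift_mm = 0,
               cupping_hu = 0, hu_shift = 0, noise_sd = 0, ...)

identity_case <- function() cached("identity_case", generate_case(identity_params(), seed = 1, compute_dose = FALSE))

# fast registration settings for unit tests
fast_config <- function()
  adaptcheck_config(registration = registration_config(
    max_iterations = c(120L, 80L, 40L), bspline_iterations = c(20L, 12L)))

# uniform dose volume helper
uniform_dose <- function(gy, n = c(10, 10, 10), prescription = 45) {
  g <- image_grid(n, 2, rep(0, 3))
  dose_volume(array(gy, n), g, prescription = prescription)
}

# Crafted report inputs: a 1000-voxel CTV/PTV with an exact hot fraction.
boundary_report <- function(frac_hot, hot = 46, cold = 43) {
  n <- c(10, 10, 10)
  g <- image_grid(n, 2, rep(0, 3))
  m <- array(TRUE, n)
  ss <- structure_set(list(CTV = m, PTV = m), g)
  vals <- array(hot, n)
  ncold <- round((1 - frac_hot) * 1000)
  if (ncold > 0) vals[seq_len(ncold)] <- cold
  df <- dose_volume(vals, g, prescription = 45)
  do <- dose_volume(array(hot, n), g, prescription = 45)
  plan <- plan_info(isocenter = c(0, 0, 0), prescription_dose = 45)
  evaluate_fraction(df, ss, do, ss, plan)
}
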