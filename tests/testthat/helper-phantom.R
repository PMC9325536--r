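# Shared fixtures: small phantoms and derived feature objects, built once
# per test run and cached (fixtures are generated in code, never stored).

small_params <- function(...) {
  phantom_params(grid_shape = c(24, 24, 24), spacing_mm = c(2, 2, 2),
                 tumor_radius_mm = 13, tumor_radius_sd = 1,
                 n_fat_spheres = 8, ...)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_case <- function() {
  fixture("small_case", function() generate_case(small_params(), 1, 101))
}

# one small case with its PET discretization and window-5 feature maps
small_pet_maps <- function() {
  fixture("small_pet_maps", function() {
    cs <- small_case()
    disc <- discretize(cs$images$PET, cs$roi, default_schemes(cs, "PET")$PET)
    list(case = cs, disc = disc,
         maps = extract_feature_maps(disc, cs$images$PET, cs$roi, window = 5))
  })
}

# small cohort with PET-only feature table (window 5)
small_cohort_tab <- function() {
  fixture("small_cohort_tab", function() {
    cases <- generate_cohort(n = 12, prevalence = 0.5,
                             params = small_params(), seed = 77)
    list(cases = cases,
         tab = cohort_feature_table(cases, modalities = "PET", window = 5))
  })
}

# synthetic Gaussian cohort table (no images): n patients, k features, the
# first `informative` features shifted by `effect` in class 1
gaussian_table <- function(n = 40, k = 6, informative = 0, effect = 0,
                           prevalence = 0.4, seed = 1) {
  n1 <- floor(n * prevalence)
  label <- c(rep(1L, n1), rep(0L, n - n1))
  withr::with_seed(seed, {
    tb <- tibble::tibble(patient_id = sprintf("p%03d", seq_len(n)),
                         label = label)
    for (j in seq_len(k)) {
      tb[[paste0("f", j)]] <- stats::rnorm(n) +
        if (j <= informative) effect * label else 0
    }
    tb
  })
}
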