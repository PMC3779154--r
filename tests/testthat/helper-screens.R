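# Shared fixture builders. Everything is generated in code under fixed
# seeds; the heavier screens are built lazily and memoised per test run.

the_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = the_cache)) {
    assign(key, force(expr), envir = the_cache)
  }
  get(key, envir = the_cache)
}

# 8-point assay series used throughout
assay_series <- function() make_series(57, 5, 8)

# noiseless single-sample screen of pure pan-cytotoxic compounds
noiseless_screen <- function() {
  memo("noiseless", {
    truth <- generate_library(12, fractions = c(pan_cytotoxic = 1),
                              samples = sample_manifest(1, 0), seed = 11)
    raw <- generate_sample_screen(
      truth, "CLL01",
      noise = noise_model(well_cv = 0, spatial_amplitude = 0), seed = 11
    )
    list(truth = truth, raw = raw,
         norm = normalize_stack(pattern_correct(raw)))
  })
}

# the default 64-compound mini screen, run end to end once
mini_screen <- function() {
  memo("mini", {
    run_pipeline(mini_screen_config(), file.path(tempdir(), "mini_fixture"))
  })
}

# tiny hand-built activity matrix for hit-calling unit tests
toy_matrix <- function() {
  tibble::tibble(
    compound_id = rep(c("A", "B", "C", "D"), each = 3),
    sample_id = rep(c("CLL01", "CLL02", "NRM01"), times = 4),
    category = c(
      "active", "active", "inactive",      # A: consensus, normal-inactive
      "active", "inconclusive", "active",  # B: not pan-active in CLL
      "active", "active", "active",        # C: consensus, toxic to normal
      "inactive", "inactive", "inactive"   # D: inactive everywhere
    ),
    curve_class = c("1.1", "1.1", "4",
                    "1.1", "3", "1.1",
                    "1.2", "1.2", "1.2",
                    "4", "4", "4"),
    ic50 = c(0.5, 1, NA,
             2, NA, 3,
             4, 5, 4.5,
             NA, NA, NA),
    efficacy = c(95, 92, 3, 90, 40, 88, 75, 70, 72, 2, 1, 0)
  )
}
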