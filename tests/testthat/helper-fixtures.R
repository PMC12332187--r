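# Shared fixtures, built in code. Expensive end-to-end runs are memoised in
# a session-level environment so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  v <- .fixture_env[[name]]
  if (is.null(v)) {
    v <- builder()
    .fixture_env[[name]] <- v
  }
  v
}

# A tiny mixture + schedule + model for engine-level tests (fast: ~10 cycles)
tiny_world <- function(n_bg = 40L, n_spike = 8L, gradient_min = 1,
                       seed = 101L, ratio = 1 / 16) {
  model <- signal_model(gradient_min = gradient_min,
                        profile_seed = hash_seed(seed, "profiles"))
  bg <- generate_peptidome(n_bg, hash_seed(seed, "bg"),
                           gradient_min = gradient_min, rt_margin = 0.1,
                           rt_sigma = 0.08)
  sp <- generate_peptidome(n_spike, hash_seed(seed, "sp"),
                           gradient_min = gradient_min, rt_margin = 0.1,
                           rt_sigma = 0.08, source = "spike",
                           target_fraction = 1)
  targets <- data.frame(sequence = sp$sequence, class = "target",
                        rt_min = sp$rt_apex)
  targets <- predict_rt(targets, gradient_min = gradient_min)
  sil <- schedule_targets(targets, halfwidth_min = 0.3,
                          gradient_min = gradient_min)
  mix <- make_dilution_series(bg, sp, ratio)[[1L]]
  list(model = model, bg = bg, sp = sp, targets = targets, sil = sil,
       mix = mix, gradient_min = gradient_min, seed = seed)
}

# A noise-free self-spectrum of a peptidoform (flat fragment intensities)
self_spectrum <- function(p, intensity = 100) {
  fr <- fragment_mzs(p, 1L)
  peaklist(fr$mz, rep(intensity, nrow(fr)),
           precursor_mz = precursor_mz(monoisotopic_mass(p), p$charge),
           precursor_charge = p$charge)
}

# The shared desk-scale dilution benchmark used by the acceptance tests:
# 5 paired seeds at the strongest dilution, plus a spike-free negative
# control, under the package's default study conditions.
acceptance_bench <- function() {
  fixture("acceptance_bench", function() {
    benchmark_dilution(benchmark_config(ratios = c(1 / 1024, 0),
                                        n_replicates = c(5L, 1L),
                                        seed = 20260930L))
  })
}
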