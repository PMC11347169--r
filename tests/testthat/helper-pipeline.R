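# Shared helpers: run the full pipeline (simulate -> noise -> two-pass
# segment -> per-trace stats) for one condition and seed, at a given size.

pipeline_seed <- function(base, k) (base * 97L + k * 1009L) %% 2000000011L

run_pipeline <- function(preset_name, seed, n_traces) {
  p <- default_presets(preset_name)[[1]]
  np <- characterize_noise(lapply(1:3, function(i) {
    simulate_baseline(p$noise_sd, 200, seed = pipeline_seed(seed, 9000 + i))
  }))
  ens <- simulate_ensemble(p, n_traces, seed = seed)
  tp <- two_pass_segment(ens$traces, np, p$geometry)
  st <- trace_statistics(tp$segments)
  list(preset = p, profile = np, ens = ens, tp = tp, stats = st,
       rates = dplyr::filter(tp$segments, kind == "event")$rate_bp_s)
}

gauss_mean_of <- function(rates) robust_rate_mean(rates)

exp_mean_of <- function(values, cutoff) {
  tryCatch(fit_exponential(values, cutoff = cutoff)$mean,
           error = function(e) NA_real_)
}

median_over_seeds <- function(n_seeds, f) {
  median(vapply(seq_len(n_seeds), function(k) f(1000L + 13L * k),
                numeric(1)), na.rm = TRUE)
}
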