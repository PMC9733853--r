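# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small heterogeneous cohort: 3 subjects, full task set
small_cohort <- function() {
  cached("small_cohort", function() {
    simulate_cohort(cohort_config(n_subjects = 3, master_seed = 42))
  })
}

small_windows <- function(window_s = 10) {
  cached(paste0("small_windows_", window_s), function() {
    wc <- windowing_config(window_s)
    unlist(lapply(small_cohort(), function(s)
      segment_windows(s$recording, s$annotations, wc)), recursive = FALSE)
  })
}

small_fm <- function(domain = "timefreq", window_s = 10) {
  cached(paste0("small_fm_", domain, "_", window_s), function() {
    build_feature_matrix(small_windows(window_s), domain)
  })
}

# study-scale cohort used by the pipeline-recovery checks:
# 10 subjects, 10 s windows, time-frequency features
recovery_cohort_fm <- function(heterogeneous = TRUE) {
  key <- paste0("recovery_fm_", heterogeneous)
  cached(key, function() {
    het <- if (heterogeneous) list(amp_sdlog = 0.15, freq_jitter_max = 0.15,
                                   rot_max_deg = 20)
           else list(amp_sdlog = 0, freq_jitter_max = 0, rot_max_deg = 0)
    cfg <- cohort_config(n_subjects = 10, master_seed = 101, heterogeneity = het)
    co <- simulate_cohort(cfg)
    wc <- windowing_config(10)
    wins <- unlist(lapply(co, function(s)
      segment_windows(s$recording, s$annotations, wc)), recursive = FALSE)
    build_feature_matrix(wins, "timefreq")
  })
}

# reduced random-forest configuration for pipeline-scale runs
recovery_rf_config <- function(seed = 3L) {
  model_config("rf", grid = list(max_depth = c(10L, 20L), mtry = c(20L, 40L)),
               num_trees = 200L, seed = seed)
}

# a single deterministic window built directly (no simulation)
make_window <- function(samples, window_s = NULL, fs = 32,
                        label = "walking", subject_id = "T01") {
  samples <- as.matrix(samples)
  if (is.null(window_s)) window_s <- nrow(samples) / fs
  structure(list(subject_id = subject_id, label = label, start_s = 0,
                 window_s = window_s, sampling_rate = fs, samples = samples),
            class = "window")
}

sine_window <- function(freq, amp = 1, L = 320, fs = 32, axis = 1,
                        noise = 0, seed = 1) {
  set.seed(seed)
  t <- (seq_len(L) - 1) / fs
  m <- matrix(stats::rnorm(L * 3, 0, noise), L, 3)
  m[, axis] <- m[, axis] + amp * sin(2 * pi * freq * t)
  make_window(m, fs = fs)
}
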