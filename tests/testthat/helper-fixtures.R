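# Shared fixtures, built once per test run.

# small scene for module tests (fast); default-size runs live in the
# acceptance suite
small_scene_cache <- new.env(parent = emptyenv())
small_scene <- function(seed = 7L, rows = 60L, cols = 60L) {
  key <- sprintf("s_%d_%d_%d", seed, rows, cols)
  if (is.null(small_scene_cache[[key]]))
    small_scene_cache[[key]] <- generate_scene(
      scene_config(grid_rows = rows, grid_cols = cols, seed = seed))
  small_scene_cache[[key]]
}

# planted linear benchmark: 5 independent informative variables among p,
# response = their sum plus noise at half the signal's spread
planted_design <- function(seed, n = 300L, p = 44L, n_inf = 5L,
                           noise_frac = 0.5) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- sprintf("v%02d", seq_len(p))
  signal <- rowSums(X[, seq_len(n_inf), drop = FALSE])
  y <- signal + stats::rnorm(n, sd = noise_frac * stats::sd(signal))
  list(samples = paired_samples(X, y),
       informative = sprintf("v%02d", seq_len(n_inf)))
}

# memoized default-size pipeline run used by the end-to-end suites
default_run_cache <- new.env(parent = emptyenv())
default_pipeline_run <- function() {
  if (is.null(default_run_cache$res))
    default_run_cache$res <- run_pipeline(pipeline_config(seed = 42L))
  default_run_cache$res
}

expect_all_close <- function(a, b, tol) {
  expect_true(max(abs(a - b), na.rm = TRUE) <= tol)
}
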