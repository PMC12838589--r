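# Shared fixtures: all synthetic, built in code at test time.

tiny_spec <- function(grid = 12L, seed = 0L) {
  phantom_spec(grid_shape = rep(grid, 3),
               tumor_radii = c(core = 1.5, rim = 2.5, edema = 3.8),
               seed = seed)
}

tiny_styles <- function() benchmark_styles(base_noise = 0.05)

tiny_dataset <- function(n = 6L, grid = 12L, seed = 1L) {
  build_dataset(tiny_spec(grid), tiny_styles(), n_per_domain = n, seed = seed)
}

tiny_model_config <- function(channels = 8L, ...) {
  encoder_config(channels = channels, conv_depth = 2L, transformer_depth = 1L,
                 seg_head = FALSE, ...)
}

tiny_train_config <- function(grid = 12L, epochs = 2L, ...) {
  damlm_config(epochs = epochs, patch_shape = grid, patch_stride = grid,
               lambda_seg = 0, augment = FALSE, patience = 100L, ...)
}

# a single small trained model shared by evaluation/robustness tests
.test_cache <- new.env(parent = emptyenv())
trained_tiny_fit <- function() {
  if (is.null(.test_cache$fit)) {
    ds <- build_dataset(tiny_spec(grid = 16L), tiny_styles(),
                        n_per_domain = 20L, seed = 7L)
    fit <- damlm_fit(ds, tiny_model_config(channels = 8L),
                     tiny_train_config(grid = 16L, epochs = 6L),
                     adaptation_weights(), seed = 1L)
    .test_cache$fit <- fit
    .test_cache$ds <- ds
  }
  list(fit = .test_cache$fit, ds = .test_cache$ds)
}

# random 4-channel patch
rand_patch <- function(grid = 8L, C = 4L, seed = 1L) {
  set.seed(seed)
  array(rnorm(grid^3 * C), dim = c(rep(grid, 3), C))
}

# central finite differences of f (scalar) w.r.t. one entry of a flat list
fd_grad_entry <- function(f, params, name, idx = 1L, h = 1e-5) {
  up <- params; up[[name]][idx] <- up[[name]][idx] + h
  dn <- params; dn[[name]][idx] <- dn[[name]][idx] - h
  (f(up) - f(dn)) / (2 * h)
}
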