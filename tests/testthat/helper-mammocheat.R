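# Shared fixtures, built in code. Cohorts are memoized so several test files
# can reuse the same phantoms without regenerating them.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

tiny_cohort <- function() memoize("tiny_cohort", generate_cohort(
  cohort_spec(8, 0, 8, seed = 21, image_size = 64)))

small_cohort <- function() memoize("small_cohort", generate_cohort(
  cohort_spec(30, 15, 15, seed = 11, image_size = 128)))

# noise-free cohort with exact analytic ground truth
clean_cohort <- function() memoize("clean_cohort", generate_cohort(
  cohort_spec(25, 12, 13, seed = 31, image_size = 128, noise_sd = 0)))

# a CNN small enough for plumbing tests (50x50 input, one conv block)
tiny_cnn_config <- function(seed = 1L)
  cnn_config(input_size = c(50L, 50L), conv_filters = 4L, kernel = 3L,
             pool = 2L, dense_units = 8L, dropout = 0, batch_size = 8L,
             epochs = 1L, seed = seed)

# separable 100x100 task: dark images (label 0) vs bright images (label 1)
separable_task <- function(n = 40, seed = 3) {
  withr::with_seed(seed, {
    imgs <- lapply(seq_len(n), function(i) {
      base <- if (i <= n / 2) 60 else 190
      quantize8(matrix(base + rnorm(1e4, 0, 10), 100, 100))
    })
    list(images = imgs, labels = rep(c(0, 1), each = n / 2))
  })
}

quantize8 <- function(x) {
  x <- round(x); x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}
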