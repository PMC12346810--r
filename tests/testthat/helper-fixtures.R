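# Shared fixtures built in code. The small phantom cohort is generated once
# per test session and reused across files.

small_cohort_params <- function(seed = 11L) {
  cohort_params(n_train = 8L, n_test = 6L, grid_dims = c(32L, 32L, 24L),
                organ_semiaxes_mm = c(9, 9, 22), seed = seed)
}

small_cohort <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      dir <- file.path(tempdir(), "radpipe-small-cohort")
      cached <<- generate_cohort(small_cohort_params(), dir)
    }
    cached
  }
})

# full-size study cohort (default conditions), generated once per session
default_cohort <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      dir <- file.path(tempdir(), "radpipe-default-cohort")
      cached <<- generate_cohort(cohort_params(), dir)
    }
    cached
  }
})

# uniform random volume/mask pair on a shared grid
random_volume_mask <- function(seed, dims = c(5L, 4L, 3L),
                               spacing = c(0.7, 0.7, 3.0)) {
  set.seed(seed)
  vol <- volume_grid(array(stats::runif(prod(dims), -300, 300), dims),
                     spacing = spacing)
  labs <- array(sample(0:2, prod(dims), replace = TRUE), dims)
  list(volume = vol,
       mask = mask_grid(labs, spacing = spacing))
}
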