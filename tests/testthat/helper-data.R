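# Shared fixtures, built in code and memoised per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  hit <- fixture_env[[key]]
  if (!is.null(hit)) return(hit)
  val <- fn()
  fixture_env[[key]] <- val
  val
}

# small vessel dataset for fast smoke tests (64^2)
tiny_vessel_data <- function() {
  memo("vessel64", function() {
    generate_dataset(synth_config(size = 64L, n_images = 8L, seed = 101L),
                     "vessel")
  })
}

# small graded dataset (64^2)
tiny_dr_data <- function() {
  memo("dr64", function() {
    generate_dataset(synth_config(size = 64L, n_images = 10L, seed = 102L),
                     "dr")
  })
}

tiny_mtnet <- function(seed = 5L) {
  ret_instantiate(build_mtnet(hyper = ret_tiny_hyper()), seed = seed)
}

rand_image_batch <- function(h, w, n = 1L, seed = 1L) {
  set.seed(seed)
  array(stats::runif(h * w * 3 * n), c(h, w, 3L, n))
}

# quick confusion constructor for metric tests
cc <- function(tp, fp, tn, fn) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "ret_confusion")
}
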