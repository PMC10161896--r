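# Shared fixtures, all generated in code under fixed seeds. Heavier
# objects (datasets, trained models) are memoised so several test files
# can reuse one instance.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

rand_mat <- function(h, w, seed = 1L) {
  destriper:::with_seed(seed, matrix(stats::rnorm(h * w), h, w))
}

# A small paired dataset: 32 px phantoms, 32 angles -> 32 x 32 sinograms.
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    build_dataset(n_total = 14L, train_fraction = 10 / 14, size_px = 32L,
                  angles = default_angles(32L, 0, 179), seed = 42L)
  })
}

# One mid-size sample record with even dimensions (40 angles x 32 det).
one_record <- function() {
  fixture("one_record", function() {
    ph <- make_phantom(32L, seed = 7L)
    add_stripes(radon(ph, default_angles(40L, 0, 179)), stripe_spec(seed = 3L))
  })
}

# A model with every parameter zero (identity corrector).
zero_model <- function() {
  m <- build_model(init_seed = 1L)
  params <- destriper:::flatten_params(m)
  destriper:::unflatten_params(m, lapply(params, function(p) p * 0))
}

run_python <- function(code, input) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  out <- system2("python", script, stdout = TRUE, stderr = TRUE,
                 input = input)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  }
  out
}
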