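# Shared cache for expensive fixture simulations so several test files can
# reuse the same runs (testthat loads helpers once per test_dir run).
if (!exists(".gl_cache", inherits = FALSE)) .gl_cache <- new.env()

cached <- function(key, expr) {
  if (!exists(key, envir = .gl_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .gl_cache)
  }
  get(key, envir = .gl_cache, inherits = FALSE)
}
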