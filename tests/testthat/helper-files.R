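local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("pathmoe")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

local_tempfile <- function(env = parent.frame()) {
  f <- tempfile("pathmoe", fileext = ".txt")
  withr::defer(unlink(f), envir = env)
  f
}
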