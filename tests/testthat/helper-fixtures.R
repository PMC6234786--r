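# Small in-code fixtures shared across test files.

balanced4 <- function() {
  ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
}

caterpillar3 <- function() {
  ape::read.tree(text = "((a:1,b:1):1,c:2);")
}

write_tmp <- function(lines, ext = ".nwk") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

regions4 <- function(codes = c("A", "B", "A", "A")) {
  region_table(c("a", "b", "c", "d"), codes)
}

# One small fixture bundle reused by pipeline/regional tests (module scope).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- dryland_fixture(seed = 3, n_posterior = 10, crown_age = 30,
                                lambda = c(0.2, 0.1), shift_times = 8)
    }
    cache
  }
})
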