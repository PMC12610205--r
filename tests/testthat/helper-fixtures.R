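# tiny in-code fixtures shared across test files

# a two-level grayscale image: n_lo pixels at lo, n_hi at hi (row-filled)
two_level_image <- function(lo = 10L, hi = 200L, n_lo = 100L, n_hi = 100L,
                            ncol = 20L) {
  v <- c(rep(lo, n_lo), rep(hi, n_hi))
  matrix(as.integer(v), ncol = ncol)
}

# binary mask with a filled rectangle block
rect_mask <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(0L, h, w)
  m[r0:r1, c0:c1] <- 1L
  m
}

# default small analysis config used widely in tests: the synthetic disks
# (radius 10-18) have areas ~320-1000 px, inside the default gate
test_config <- function(...) quant_config(...)
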