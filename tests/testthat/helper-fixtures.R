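# Shared fixtures: tiny network configurations and layouts used across tests.

tiny_config <- function(dropout_rate = 0.1, seed = 7L) {
  net_config(levels = 2L, base_width = 6L, bottleneck_factor = 2L,
             blocks_per_level = 1L, compression_widths = c(3L, 4L),
             dropout_rate = dropout_rate, seed = seed)
}

two_class_layout <- function(h = 32L, w = 32L) {
  # TUM | NEC split at the vertical midline
  synth_layout(c(h, w), list(
    region_rect(0L, 0L, 0L, h, w),
    region_rect(2L, 0L, w %/% 2L, h, w - w %/% 2L)
  ))
}

random_label_map <- function(h, w) {
  matrix(sample(0:7, h * w, replace = TRUE), h, w)
}

random_prob_map <- function(h, w, k = 8L) {
  m <- matrix(stats::rexp(h * w * k), h * w, k)
  array(m / rowSums(m), c(h, w, k))
}
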