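# Small programmatic fixtures shared across tests.

# deterministic pseudo-random 8-bit image
rand_image <- function(h, w = h, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

const_image <- function(h, w = h, value = c(10, 20, 30)) {
  array(rep(value, each = h * w), dim = c(h, w, 3))
}

# tiny labeled set: n images, first n_pos positive
tiny_set <- function(n = 4, n_pos = 2, size = 16, seed = 1) {
  imgs <- lapply(seq_len(n), function(i) rand_image(size, seed = seed + i))
  image_set(imgs, labels = as.integer(seq_len(n) <= n_pos),
            ids = sprintf("img_%03d", seq_len(n)))
}
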