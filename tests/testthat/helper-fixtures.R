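# Shared fixtures: all test data is generated in code, none stored on disk.

# Easy desk-scale phantoms: small, high contrast, low noise.
make_phantoms <- function(n, seed0, image_size = 64L, n_nodules = c(1L, 2L),
                          radius = c(4, 9), benign_fraction = 0.5,
                          spiculation = 0.4) {
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(image_size = image_size, n_nodules = n_nodules,
                       benign_fraction = benign_fraction,
                       nodule_radius_range = radius,
                       spiculation_amplitude = spiculation,
                       background_noise_sigma = 0.01, nodule_contrast = 0.4,
                       seed = seed0 + i)
    generate_phantom(sp)
  })
}

# A tiny random binary mask as an integer matrix.
random_binary_mask <- function(h = 8, w = h, p = 0.4) {
  m <- matrix(rbinom(h * w, 1, p), h, w)
  storage.mode(m) <- "integer"
  m
}

# Brute-force set-overlap statistics from first principles: enumerate
# pixels, never reuse the package's arithmetic.
brute_overlap <- function(pred, truth) {
  xs <- which(pred == 1)
  ys <- which(truth == 1)
  list(inter = length(intersect(xs, ys)),
       union = length(union(xs, ys)),
       nx = length(xs), ny = length(ys))
}

# Exhaustive pairwise AUC: P(score_pos > score_neg) with ties counted 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Minimal toy network for loss/gradient tests: conv -> sigmoid on a 4x4.
make_toy_segnet <- function(seed = 3) {
  g <- ctnodule:::nn_graph()
  x <- ctnodule:::nn_add(g, "input", size = 4L, channels = 1L)
  h <- ctnodule:::nn_add(g, "conv", x, cout = 2L, k = 3L)
  h <- ctnodule:::nn_add(g, "swish", h)
  h <- ctnodule:::nn_add(g, "conv", h, cout = 1L, k = 1L)
  ctnodule:::nn_add(g, "sigmoid", h)
  list(graph = g, params = ctnodule:::nn_init(g, seed))
}
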