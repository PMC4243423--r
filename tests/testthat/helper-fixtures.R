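# Small in-code fixtures shared across test files.

tiny_cube <- function(M = 4L, N = 5L, K = 3L, seed = 42L, stage = "raw") {
  set.seed(seed)
  hyper_cube(array(runif(M * N * K), c(M, N, K)),
             wavelengths_nm = seq(400, 1000, length.out = K), stage = stage)
}

# a quick small phantom; noise switched off unless asked for
small_phantom <- function(M = 60L, N = 80L, K = 8L, sigma = 0,
                          impulse_density = 0, stripe_jitter = 0L,
                          lighting_tilt = 0.2, seed = 7L, ...) {
  phantom_spec(M = M, N = N, K = K, sigma = sigma,
               impulse_density = impulse_density,
               stripe_jitter = stripe_jitter,
               lighting_tilt = lighting_tilt, seed = seed, ...)
}

# a cube with a clean stripe (rows 1..edge[n] at `bright`) over a flat scene
stripe_cube <- function(M = 30L, N = 12L, K = 3L, edge = 10L, bright = 0.9,
                       scene = 0.3) {
  if (length(edge) == 1L) edge <- rep(edge, N)
  a <- array(scene, c(M, N, K))
  for (n in seq_len(N)) a[seq_len(edge[n]), n, ] <- bright
  hyper_cube(a, seq(400, 700, length.out = K))
}
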