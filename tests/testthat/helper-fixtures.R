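# Shared fixtures, built once per test session (lazy cache).

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# large flat phantom: edge effects negligible for displacement statistics
flat_phantom <- function() fx_get("flat_phantom", function()
  make_phantom(size_px = 256, pixel_size = 0.1, n_domains = 0,
               domain_radius = 0.3, contrast = 0, seed = 1))

# structured phantom with chromatin-dense domains
cd_phantom <- function() fx_get("cd_phantom", function()
  make_phantom(size_px = 256, pixel_size = 0.1, n_domains = 40,
               domain_radius = 0.3, contrast = 2, seed = 1))

cd_map <- function() fx_get("cd_map", function() {
  ph <- cd_phantom()
  density_map(ph$density, ph$mask, ph$pixel_size)
})

# moderate p53-like simulation shared by HMM / mapping tests
p53_sim <- function() fx_get("p53_sim", function()
  simulate_tracks(cd_phantom(), preset_p53like(n_tracks = 4000, n_frames = 50,
                                               seed = 11)))

p53_hmm <- function() fx_get("p53_hmm", function()
  fit_hmm(p53_sim(), dt = 0.01, K = 3, min_len = 8, n_restarts = 6, seed = 2))

# uniform random positions inside a map's mask, with in-pixel jitter
uniform_positions <- function(map, n, seed) {
  with_seed <- get("with_seed", envir = asNamespace("smtmsim"))
  with_seed(seed, {
    idx <- which(map$mask)
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    ps <- map$pixel_size
    cbind(((pick - 1L) %/% nrow(map$mask)) * ps + runif(n, -ps / 2, ps / 2),
          ((pick - 1L) %% nrow(map$mask)) * ps + runif(n, -ps / 2, ps / 2))
  })
}
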