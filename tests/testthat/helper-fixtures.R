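# fixtures built in code; everything is seeded and small

random_cube <- function(M = 8, N = 9, B = 12, seed = 1, name = "fixture") {
  set.seed(seed)
  hyper_cube(array(runif(M * N * B), c(M, N, B)), name = name)
}

random_mask <- function(M = 8, N = 9, C = 4, seed = 1, unlabeled = 0L,
                        class_names = c("normal", "tumor", "vessel",
                                        "background")[seq_len(C)]) {
  set.seed(seed)
  label_mask(matrix(sample(0:C, M * N, replace = TRUE), M, N),
             class_names, unlabeled)
}

# small ready-made synthetic scene reduced to 3 factor bands, with patches
# and a split; cached per seed within a test run
small_scene_pipeline <- function(seed = 1, M = 24, N = 24, B = 12,
                                 labeled_fraction = 0.5) {
  lib <- make_spectral_library(4, B, separation = 10, seed = seed)
  sc <- generate_scene(scene_spec(M, N, B, labeled_fraction, seed = seed),
                       lib)
  red <- suppressMessages(reduce_bands_fa(sc$cube, 3, seed = seed))
  pset <- extract_patches(red, sc$mask, 3)
  split <- stratified_split(pset, seed = seed)
  list(lib = lib, scene = sc, reduced = red, pset = pset, split = split)
}

# independent cosine similarity oracle (never calls scs_score)
cosine_oracle <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
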