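# Shared fixtures, built in code: small standardized scene sets for the
# two benchmark species, and the desk-scale forgetting experiment used by
# the training tests and the acceptance suite.

species_a <- function() species_spec("A", 5, "disk", contrast = -70)
species_b <- function() species_spec("B", 8, "ring", contrast = +70)

# n_scenes standardized 64x64 scenes of one species with ground truth in
# preprocessed coordinates (identity scale: scenes are generated at the
# target width).
make_species_set <- function(sp, n_scenes, seed0, size_px = 64L,
                             n_particles = 5L, noise = 10) {
  pc <- if (size_px >= 64L) preprocess_config(target_width = size_px)
  imgs <- vector("list", n_scenes)
  anns <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    s <- make_particle_scene(scene_spec(
      width = size_px, height = size_px, n_particles = n_particles,
      species = list(sp), noise_sigma = noise,
      min_separation = if (size_px < 64L) 8 else 14,
      seed = seed0 + i))
    # below the standardizable width (speed fixtures) the raw scene is
    # already on the 0-255 gray scale; use it directly
    imgs[[i]] <- if (is.null(pc)) s$micrograph else
      standardize(s$micrograph, pc)
    a <- s$annotations
    a$coordinate_space <- "preprocessed"   # scale 1: already at target width
    anns[[i]] <- a
  }
  list(images = imgs, anns = anns)
}

# Joint-train on species A, then fine-tune and continual-learn on species
# B; returns the AP values of the three resulting models on held-out
# scenes of both species.
run_forgetting_seed <- function(seed, iters = 300L, lr = 1e-3,
                                n_train = 16L, n_test = 8L) {
  trA <- make_species_set(species_a(), n_train, seed * 1000)
  trB <- make_species_set(species_b(), n_train, seed * 1000 + 500)
  teA <- make_species_set(species_a(), n_test, seed * 1000 + 700)
  teB <- make_species_set(species_b(), n_test, seed * 1000 + 800)
  dsA <- particle_dataset("A", trA$images, trA$anns, particle_size = 10)
  dsB <- particle_dataset("B", trB$images, trB$anns, particle_size = 16)

  jt <- train_joint(dsA, train_config("joint", iterations = iters,
                                      batch_size = 4, learning_rate = lr,
                                      seed = seed))
  ft <- train_finetune(jt$model, dsB,
                       train_config("finetune", iterations = iters,
                                    batch_size = 4, learning_rate = lr,
                                    seed = seed + 1))
  cl <- train_continual(jt$model, jt$store, dsB,
                        train_config("continual", iterations = iters,
                                     batch_size = 4, learning_rate = lr,
                                     seed = seed + 1))
  c(apA_joint = evaluate_model(jt$model, teA$images, teA$anns, 10)$ap,
    apA_ft = evaluate_model(ft, teA$images, teA$anns, 10)$ap,
    apA_cl = evaluate_model(cl$model, teA$images, teA$anns, 10)$ap,
    apB_ft = evaluate_model(ft, teB$images, teB$anns, 16)$ap,
    apB_cl = evaluate_model(cl$model, teB$images, teB$anns, 16)$ap)
}
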