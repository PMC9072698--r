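test_that("exemplar selection keeps a contiguous run of the requested size", {
  # 10 micrographs x 100 annotations, in file order
  anns <- lapply(1:10, function(m)
    annotation_set(x = seq_len(100) + 1000 * m, y = rep(1, 100),
                   coordinate_space = "preprocessed"))
  mics <- lapply(1:10, function(m) matrix(0, 8, 8))
  e <- build_exemplar("d1", mics, anns, n = 200, seed = 4)
  expect_equal(e$n_annotations, 200)
  expect_equal(sum(vapply(e$annotations, n_annotations, 0L)), 200)
  # contiguity: selected x values form one consecutive run in file order
  xs <- unlist(lapply(e$annotations, function(a) a$records$x))
  all_xs <- unlist(lapply(anns, function(a) a$records$x))
  start <- match(xs[1], all_xs)
  expect_equal(xs, all_xs[start:(start + 199)])
  # fewer annotations than requested: keep everything
  e2 <- build_exemplar("d2", mics[1:2],
                       lapply(anns[1:2], function(a) {
                         a$records <- a$records[1:75, ]; a
                       }), n = 200, seed = 1)
  expect_equal(e2$n_annotations, 150)
  # determinism
  e3 <- build_exemplar("d1", mics, anns, n = 200, seed = 4)
  expect_identical(e$annotations, e3$annotations)
  expect_error(build_exemplar("d3", mics[1],
                              list(annotation_set()), n = 200), "empty")
})

test_that("the exemplar store grows immutably", {
  st <- exemplar_store()
  mics <- list(matrix(0, 8, 8))
  anns <- list(annotation_set(x = 1:10, y = 1:10,
                              coordinate_space = "preprocessed"))
  e1 <- build_exemplar("A", mics, anns, n = 5, seed = 1)
  st <- store_add(st, e1)
  expect_error(store_add(st, e1), "immutable")
  old_entry <- st$entries$A
  e2 <- build_exemplar("B", mics, anns, n = 5, seed = 2)
  st2 <- store_add(st, e2)
  expect_length(st2$entries, 2)
  expect_identical(st2$entries$A, old_entry)
})

test_that("flips are exact involutions on image and coordinates", {
  set.seed(6)
  img <- matrix(runif(32 * 48, 0, 255), 32, 48)   # W=48, H=32
  ann <- annotation_set(x = c(0, 10.5, 47), y = c(3, 20.25, 31),
                        coordinate_space = "preprocessed")
  f1 <- flip_horizontal(img, ann)
  expect_equal(f1$ann$records$x, c(47, 36.5, 0))
  f2 <- flip_horizontal(f1$image, f1$ann)
  expect_identical(f2$image, img)
  expect_equal(f2$ann$records$x, ann$records$x)
  v2 <- flip_vertical(flip_vertical(img, ann)$image,
                      flip_vertical(img, ann)$ann)
  expect_identical(v2$image, img)
})

test_that("crops shift coordinates and drop outside annotations", {
  img <- matrix(0, 1024, 1024)
  ann <- annotation_set(x = c(600, 100), y = c(600, 100),
                        coordinate_space = "preprocessed")
  r <- crop_scene(img, ann, c(0, 0), c(512, 512))
  expect_equal(n_annotations(r$ann), 1)       # (600,600) dropped
  expect_equal(r$ann$records$x, 100)
  r2 <- crop_scene(img, ann, c(50, 50), c(512, 512))
  expect_equal(r2$ann$records$x[r2$ann$records$y == 50], 50)
  expect_error(crop_scene(img, ann, c(0, 0), c(4, 4)), "smaller")
  # augment with a fixed seed is reproducible
  a1 <- augment(img, ann, list(flip = TRUE, crop = TRUE), seed = 3,
                crop_size = c(512, 512))
  a2 <- augment(img, ann, list(flip = TRUE, crop = TRUE), seed = 3,
                crop_size = c(512, 512))
  expect_identical(a1, a2)
})

test_that("zero training epochs leave the parameters untouched", {
  sets <- make_species_set(species_a(), 2, 8100, size_px = 32L,
                           n_particles = 2L)
  ds <- particle_dataset("A", sets$images, sets$anns, 10)
  cfg <- detector_config(trunk_channels = c(2L, 2L, 2L), head_channels = 2L)
  m <- new_detector(cfg, seed = 3)
  m2 <- train_finetune(m, ds, train_config("finetune", epochs = 0L,
                                           seed = 1))
  expect_identical(model_parameters(m2), model_parameters(m))
})

test_that("training reduces the loss and is reproducible under a seed", {
  sets <- make_species_set(species_a(), 6, 8200, size_px = 32L,
                           n_particles = 2L)
  ds <- particle_dataset("A", sets$images, sets$anns, 10)
  cfg <- train_config("joint", iterations = 80L, batch_size = 2L,
                      learning_rate = 1e-3, seed = 5,
                      detector = detector_config(
                        trunk_channels = c(4L, 6L, 8L),
                        head_channels = 8L))
  jt <- train_joint(ds, cfg)
  h <- jt$model$history
  expect_lt(mean(tail(h$total, 10)), mean(head(h$total, 10)))
  expect_length(jt$store$entries, 1)
  jt2 <- train_joint(ds, cfg)
  expect_identical(model_parameters(jt$model), model_parameters(jt2$model))
})

test_that("a continual step with no rehearsal and zero weights is fine-tuning", {
  setsA <- make_species_set(species_a(), 3, 8300, size_px = 32L,
                            n_particles = 2L)
  setsB <- make_species_set(species_b(), 3, 8400, size_px = 32L,
                            n_particles = 2L)
  dsA <- particle_dataset("A", setsA$images, setsA$anns, 10)
  dsB <- particle_dataset("B", setsB$images, setsB$anns, 16)
  dcfg <- detector_config(trunk_channels = c(2L, 3L, 4L),
                          head_channels = 4L)
  jt <- train_joint(dsA, train_config("joint", iterations = 4L,
                                      batch_size = 2L, seed = 2,
                                      detector = dcfg))
  w0 <- loss_weights(lambda_d = 0, lambda_r = 0)
  ft <- train_finetune(jt$model, dsB,
                       train_config("finetune", iterations = 6L,
                                    batch_size = 2L, seed = 9,
                                    weights = w0))
  cl <- train_continual(jt$model, jt$store, dsB,
                        train_config("continual", iterations = 6L,
                                     batch_size = 2L, seed = 9,
                                     weights = w0, exemplar_mix = 0))
  expect_identical(model_parameters(cl$model), model_parameters(ft))
})

test_that("the frozen branch stays bit-identical through a continual step", {
  setsA <- make_species_set(species_a(), 3, 8500, size_px = 32L,
                            n_particles = 2L)
  setsB <- make_species_set(species_b(), 3, 8600, size_px = 32L,
                            n_particles = 2L)
  dsA <- particle_dataset("A", setsA$images, setsA$anns, 10)
  dsB <- particle_dataset("B", setsB$images, setsB$anns, 16)
  jt <- train_joint(dsA, train_config("joint", iterations = 3L,
                                      batch_size = 2L, seed = 2,
                                      detector = detector_config(
                                        trunk_channels = c(2L, 3L, 4L),
                                        head_channels = 4L)))
  theta_before <- model_parameters(jt$model)
  store_before <- jt$store
  cl <- train_continual(jt$model, jt$store, dsB,
                        train_config("continual", iterations = 5L,
                                     batch_size = 2L, seed = 3))
  # the old model object (branch A) is untouched
  expect_identical(model_parameters(jt$model), theta_before)
  # the student actually moved
  expect_false(identical(model_parameters(cl$model), theta_before))
  # store grew by exactly one entry; the old entry is byte-identical
  expect_length(cl$store$entries, 2)
  expect_identical(cl$store$entries$A, store_before$entries$A)
  # continual learning demands a non-empty store
  expect_error(train_continual(jt$model, exemplar_store(), dsB,
                               train_config("continual", iterations = 1L)),
               "joint")
})
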