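# Preprocessing, training orchestration, evaluation, checkpoints, CLI.

tiny_dataset <- function(dir, seed = 2, n_species = 3, n_max = 14) {
  spec <- dataset_spec(n_species = n_species, n_max = n_max,
                       imbalance_exponent = 0, clutter_level = 0.15,
                       occlusion_prob = 0.1, image_size = 32, seed = seed,
                       min_count = 3)
  generate_dataset(spec, dir)
}

tiny_config <- function(refine = FALSE, ...) {
  train_config(input_size = 32, batch_size = 8, max_epochs = 2,
               warmup_epochs = 1, early_stop_patience = 2,
               backbone = "reduced", refine = refine, seed = 1, ...)
}

test_that("preprocessing resizes, crops, and normalizes as documented", {
  img <- array(stats::runif(100 * 80 * 3), c(100, 80, 3))
  set.seed(90)
  xt <- preprocess_train(img, 64)
  expect_equal(dim(xt), c(64, 64, 3))  # 80 -> round(1.1*64) = 70 shorter side

  ev <- preprocess_eval(img, 64)
  expect_equal(dim(ev), c(64, 64, 3))
  expect_identical(ev, preprocess_eval(img, 64))  # deterministic

  # fixed seed reproduces crop offsets
  set.seed(91); a <- preprocess_train(img, 64)
  set.seed(91); b <- preprocess_train(img, 64)
  expect_identical(a, b)

  # an image at the channel means normalizes to (near) zero
  gray <- array(0, c(70, 70, 3))
  for (ch in 1:3) gray[, , ch] <- pestnet:::IMAGENET_MEAN[ch]
  expect_lt(max(abs(preprocess_eval(gray, 64))), 1e-6)

  # square input center crop is centered exactly
  sq <- array(stats::runif(88 * 88 * 3), c(88, 88, 3))
  cc <- preprocess_eval(sq, 64)
  big <- pestnet:::resize_bilinear(sq, round(1.1 * 64), round(1.1 * 64))
  off <- (70 - 64) %/% 2
  ref <- pestnet:::normalize_image(big[off + 1:64, off + 1:64, , drop = FALSE])
  expect_identical(cc, ref)
})

test_that("YAML configs reject unknown keys and mirror the defaults", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("input_size: 32", "max_epochs: 40", "early_stop_patience: 4",
               "backbone: reduced"), p)
  cfg <- read_train_config(p)
  expect_equal(cfg$input_size, 32L)
  expect_equal(cfg$max_epochs, 40L)
  expect_equal(cfg$early_stop_patience, 4L)
  # untouched keys keep the documented defaults
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$weight_decay, 5e-4)
  expect_equal(cfg$label_smoothing, 0.1)
  expect_equal(cfg$adam_beta1, 0.9)
  expect_equal(cfg$adam_beta2, 0.999)
  expect_equal(cfg$batch_size, 32L)
  # patience above max_epochs is rejected
  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("max_epochs: 4", "backbone: reduced"), p2)
  expect_error(read_train_config(p2))
})

test_that("unknown YAML keys are configuration errors", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("input_size: 32", "learningrate: 0.1"), p)
  expect_error(read_train_config(p), "unknown config key")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_species: 3", "klutter: 1"), p2)
  expect_error(read_dataset_spec(p2), "unknown dataset spec key")
})

test_that("whole-network gradients match finite differences", {
  set.seed(95)
  m <- build_model(model_config(3, "reduced"), seed = 7)
  xt <- array(stats::rnorm(16 * 16 * 3), c(16, 16, 3))
  fw <- pestnet:::nn_fwd(m, xt)
  lg <- pestnet:::loss_and_dlogits(pestnet:::softmax(fw$logits), 1L, 0.5, 0.1, 2)
  g <- pestnet:::nn_bwd(m, fw$cache, lg$dlogits)
  lossfun <- function(mm) {
    f <- pestnet:::nn_fwd(mm, xt, need_cache = FALSE)
    pestnet:::loss_and_dlogits(pestnet:::softmax(f$logits), 1L, 0.5, 0.1, 2)$loss
  }
  eps <- 1e-5
  spots <- list(
    list(get = function(p) p$stem[[1]]$w,
         set = function(p, v) { dim(v) <- dim(p$stem[[1]]$w); p$stem[[1]]$w <- v; p },
         grad = g$stem[[1]]$w),
    list(get = function(p) p$stages[[1]]$bcsa$wc,
         set = function(p, v) { dim(v) <- dim(p$stages[[1]]$bcsa$wc); p$stages[[1]]$bcsa$wc <- v; p },
         grad = g$stages[[1]]$bcsa$wc),
    list(get = function(p) p$stages[[2]]$blocks[[1]]$proj$w,
         set = function(p, v) { dim(v) <- dim(p$stages[[2]]$blocks[[1]]$proj$w); p$stages[[2]]$blocks[[1]]$proj$w <- v; p },
         grad = g$stages[[2]]$blocks[[1]]$proj$w),
    list(get = function(p) p$gpp_p,
         set = function(p, v) { p$gpp_p <- v; p }, grad = g$gpp_p))
  for (sp in spots) {
    v <- sp$get(m$params)
    for (i in sample(length(v), min(3, length(v)))) {
      m2 <- m
      vv <- v; vv[i] <- vv[i] + eps; m2$params <- sp$set(m2$params, vv); lp <- lossfun(m2)
      vv[i] <- v[i] - eps; m2$params <- sp$set(m2$params, vv); lm <- lossfun(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(sp$grad[i], num, tolerance = 1e-3)
    }
  }
})

test_that("zero attention gains reproduce the attention-free forward exactly", {
  m0 <- build_model(model_config(4, "reduced", alpha = 0, beta = 0), seed = 8)
  cfg_off <- model_config(4, "reduced", attach_bcsa = FALSE)
  m_off <- build_model(cfg_off, seed = 8)
  # share every non-attention parameter
  m_off$params$stem <- m0$params$stem
  for (i in seq_along(m0$params$stages))
    m_off$params$stages[[i]]$blocks <- m0$params$stages[[i]]$blocks
  m_off$params$gpp_p <- m0$params$gpp_p
  m_off$params$head <- m0$params$head
  x <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(pestnet:::nn_fwd(m0, x, need_cache = FALSE)$logits,
                   pestnet:::nn_fwd(m_off, x, need_cache = FALSE)$logits)
})

test_that("early stopping fires after `patience` stagnant epochs", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(dir)
  # a frozen model (vanishing learning rate) cannot improve after epoch 1
  cfg <- train_config(input_size = 32, batch_size = 8, max_epochs = 10,
                      warmup_epochs = 0, early_stop_patience = 1,
                      learning_rate = 1e-15, weight_decay = 0,
                      backbone = "reduced", refine = FALSE, seed = 3)
  res <- train_model(cfg, ds$dir, ds$train, ds$val, ds$space)
  expect_equal(nrow(res$log), 2L)
  expect_true(res$stopped_early)
  expect_equal(res$best_epoch, 0L)
  # lambda log starts at lambda_max
  expect_equal(res$log$lambda[1], cfg$lambda_max)
})

test_that("training runs are reproducible and evaluation is consistent", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(dir)
  cfg <- tiny_config()
  r1 <- train_model(cfg, ds$dir, ds$train, ds$val, ds$space)
  r2 <- train_model(cfg, ds$dir, ds$train, ds$val, ds$space)
  expect_identical(r1$log, r2$log)

  ev1 <- evaluate_model(r1$model, ds$test, ds$dir, r1$space, input_size = 32)
  ev2 <- evaluate_model(r1$model, ds$test, ds$dir, r1$space, input_size = 32)
  expect_identical(ev1$species$accuracy, ev2$species$accuracy)
  expect_identical(ev1$species_pred, ev2$species_pred)

  # collapsing can only merge refined errors inside a species
  expect_gte(ev1$species$accuracy, ev1$refined$accuracy)

  # a one-sample manifest gives accuracy exactly 0 or 1
  ev_one <- evaluate_model(r1$model, ds$test[1, , drop = FALSE], ds$dir,
                           r1$space, input_size = 32)
  expect_true(ev_one$species$accuracy %in% c(0, 1))

  # checkpoints round-trip and evaluate identically
  ck_path <- file.path(dir, "best.ckpt")
  save_checkpoint(r1, ck_path)
  ck <- load_checkpoint(ck_path)
  expect_equal(ck$model$params, r1$model$params)
  ev3 <- evaluate_model(ck$model, ds$test, ds$dir, ck$space, input_size = 32)
  expect_identical(ev3$species_pred, ev1$species_pred)

  # label-space mismatch is a configuration error before any work
  wrong <- build_refined_label_space(
    data.frame(image_id = "x", species = 0L, stage = "Adult"), 0)
  expect_error(evaluate_model(r1$model, ds$test, ds$dir, wrong, input_size = 32),
               "refined classes")
})

test_that("refined training collapses to species-level evaluation", {
  dir <- withr::local_tempdir()
  spec <- dataset_spec(n_species = 2, n_max = 20, imbalance_exponent = 0,
                       clutter_level = 0.1, image_size = 32, seed = 6,
                       min_count = 2)
  ds <- generate_dataset(spec, dir)
  expect_gt(ds$space$n_refined, ds$space$n_species)
  cfg <- tiny_config(refine = TRUE)
  res <- train_model(cfg, ds$dir, ds$train, ds$val, ds$space)
  expect_equal(res$model$config$n_classes, ds$space$n_refined)
  ev <- evaluate_model(res$model, ds$test, ds$dir, res$space, input_size = 32)
  expect_gte(ev$species$accuracy, ev$refined$accuracy)
  expect_equal(ev$species$n_samples, nrow(ds$test))
})

test_that("the CLI drives generate / refine-labels / train / evaluate", {
  root <- withr::local_tempdir()
  spec_yaml <- file.path(root, "spec.yaml")
  writeLines(c("n_species: 2", "n_max: 14", "imbalance_exponent: 0",
               "clutter_level: 0.1", "image_size: 32", "min_count: 2"),
             spec_yaml)
  data_dir <- file.path(root, "data")
  expect_message(pestnet_cli(c("generate", "--spec", spec_yaml, "--out", data_dir,
                               "--seed", "4")), "wrote")
  expect_true(file.exists(file.path(data_dir, "train.csv")))

  hier <- file.path(root, "hier.json")
  expect_message(pestnet_cli(c("refine-labels", "--manifest",
                               file.path(data_dir, "train.csv"),
                               "--min-count", "2", "--out", hier)),
                 "refined classes")
  expect_s3_class(read_hierarchy(hier), "refined_label_space")

  cfg_yaml <- file.path(root, "config.yaml")
  writeLines(c("input_size: 32", "batch_size: 8", "max_epochs: 2",
               "warmup_epochs: 1", "early_stop_patience: 2",
               "backbone: reduced"), cfg_yaml)
  run_dir <- file.path(root, "run")
  expect_message(pestnet_cli(c("train", "--config", cfg_yaml, "--data", data_dir,
                               "--hierarchy", hier, "--out", run_dir,
                               "--seed", "1")), "best validation")
  expect_true(file.exists(file.path(run_dir, "best.ckpt")))
  expect_true(file.exists(file.path(run_dir, "epochs.csv")))

  report <- file.path(root, "report.json")
  expect_message(pestnet_cli(c("evaluate", "--checkpoint",
                               file.path(run_dir, "best.ckpt"),
                               "--manifest", file.path(data_dir, "test.csv"),
                               "--data", data_dir, "--report", report)),
                 "species accuracy")
  rep <- jsonlite::read_json(report)
  expect_true(rep$species$accuracy >= 0 && rep$species$accuracy <= 1)
  expect_true(file.exists(file.path(root, "confusion.csv")))

  expect_error(pestnet_cli(c("bogus")), "unknown subcommand")
  expect_error(pestnet_cli(character(0)), "usage")
})
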