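# Training and evaluation orchestration: preprocessing, AdamW with linear
# warm-up, the scheduled CE/focal objective over refined labels, early
# stopping on validation species accuracy, checkpointing, and species-level
# evaluation via prediction collapse.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

normalize_image <- function(x) {
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - IMAGENET_MEAN[ch]) / IMAGENET_STD[ch]
  x
}

resize_shorter <- function(x, target) {
  d <- dim(x)
  scale <- target / min(d[1:2])
  resize_bilinear(x, max(target, round(d[1] * scale)), max(target, round(d[2] * scale)))
}

#' Training-time preprocessing
#'
#' Resizes the shorter image side to `round(1.1 * input_size)`, takes a
#' random crop of `input_size` squared (offsets drawn from the current RNG
#' state), and normalizes with the ImageNet per-channel statistics.
#'
#' @param image RGB array in `[0, 1]`, dim `c(H, W, 3)`.
#' @param input_size Target square resolution.
#' @return Normalized array dim `c(input_size, input_size, 3)`.
#' @export
preprocess_train <- function(image, input_size = 224L) {
  x <- resize_shorter(as_fmap(image), round(1.1 * input_size))
  d <- dim(x)
  oy <- sample.int(d[1] - input_size + 1L, 1L) - 1L
  ox <- sample.int(d[2] - input_size + 1L, 1L) - 1L
  normalize_image(x[oy + seq_len(input_size), ox + seq_len(input_size), , drop = FALSE])
}

#' Evaluation-time preprocessing
#'
#' Same resize as training but with a deterministic center crop.
#'
#' @inheritParams preprocess_train
#' @return Normalized array dim `c(input_size, input_size, 3)`.
#' @export
preprocess_eval <- function(image, input_size = 224L) {
  x <- resize_shorter(as_fmap(image), round(1.1 * input_size))
  d <- dim(x)
  oy <- (d[1] - input_size) %/% 2L
  ox <- (d[2] - input_size) %/% 2L
  normalize_image(x[oy + seq_len(input_size), ox + seq_len(input_size), , drop = FALSE])
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW (beta 0.9/0.999) at
#' an initial learning rate of 1e-3 with weight decay 5e-4, batch size 32,
#' up to 500 epochs with early-stopping patience 30, label smoothing 0.1,
#' 224 px inputs, and a 5-epoch linear warm-up from lr/100.
#'
#' @param input_size,batch_size,max_epochs,learning_rate Core training knobs.
#' @param adam_beta1,adam_beta2,weight_decay AdamW settings.
#' @param label_smoothing Smoothing mass of the CE term.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param warmup_epochs Linear warm-up length (learning rate ramps from
#'   `learning_rate/100`).
#' @param lambda_max Initial CE weight of the scheduled loss (1 = start on
#'   pure cross-entropy).
#' @param gamma Focal focusing exponent.
#' @param alpha,beta BCSA gains.
#' @param seed Master seed for initialization, shuffling, and crops.
#' @param collapse_mode Refined-to-species collapse rule.
#' @param backbone Backbone variant.
#' @param refine Train on growth-stage refined labels (TRUE) or plain
#'   species labels.
#' @return A validated `train_config` list.
#' @export
train_config <- function(input_size = 224L, batch_size = 32L, max_epochs = 500L,
                         learning_rate = 1e-3, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, weight_decay = 5e-4,
                         label_smoothing = 0.1, early_stop_patience = 30L,
                         warmup_epochs = 5L, lambda_max = 1, gamma = 2,
                         alpha = 1, beta = 1, seed = 0L,
                         collapse_mode = "argmax_then_map",
                         backbone = "vovnet57", refine = TRUE) {
  cfg <- list(input_size = as.integer(input_size), batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              weight_decay = weight_decay, label_smoothing = label_smoothing,
              early_stop_patience = as.integer(early_stop_patience),
              warmup_epochs = as.integer(warmup_epochs), lambda_max = lambda_max,
              gamma = gamma, alpha = alpha, beta = beta, seed = as.integer(seed),
              collapse_mode = collapse_mode, backbone = backbone,
              refine = isTRUE(refine))
  stopifnot(cfg$input_size > 0, cfg$batch_size > 0, cfg$max_epochs >= 1,
            cfg$learning_rate > 0, cfg$early_stop_patience <= cfg$max_epochs,
            cfg$lambda_max >= 0, cfg$lambda_max <= 1, cfg$gamma >= 0)
  structure(cfg, class = "train_config")
}

#' Read a training configuration from YAML
#'
#' Unknown keys are errors (typos must not silently fall back to defaults).
#'
#' @param path Path to a YAML file whose keys mirror [train_config()].
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(train_config, obj)
}

#' Read a dataset specification from YAML
#'
#' @param path YAML file with keys mirroring [dataset_spec()].
#' @return A `dataset_spec`.
#' @export
read_dataset_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(dataset_spec))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("unknown dataset spec key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(obj$stage_mix)) obj$stage_mix <- unlist(obj$stage_mix)
  do.call(dataset_spec, obj)
}

# trivial label space: one refined class per species (no refinement)
trivial_label_space <- function(n_species) {
  new_label_space(n_species, 0:(n_species - 1L),
                  rep("residual", n_species), 0L)
}

load_images <- function(manifest, data_dir) {
  lapply(manifest$image_path, function(p) {
    fp <- file.path(data_dir, p)
    if (!file.exists(fp)) stop("cannot read image file: ", fp, call. = FALSE)
    img <- png::readPNG(fp)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
}

epoch_seed <- function(seed, t) (seed * 48271L + t * 1103L + 7L) %% 2147483629L

#' Train a classifier
#'
#' Optimizes the refined-label objective with AdamW: linear learning-rate
#' warm-up, the scheduled CE/focal mixture (schedule advanced once per
#' epoch, 0-based epoch counter), early stopping when validation species
#' accuracy fails to improve for `early_stop_patience` epochs, and
#' best-by-validation checkpoint retention. Fully seeded: the same
#' configuration and seed reproduce the epoch log exactly on CPU.
#'
#' @param config A [train_config()].
#' @param data_dir Dataset directory (image paths in manifests are relative
#'   to it).
#' @param train_manifest,val_manifest Manifest data frames.
#' @param space A `refined_label_space` consistent with the manifests
#'   (ignored and replaced by the trivial species space when
#'   `config$refine` is FALSE).
#' @return List with the best `model`, its label `space`, the epoch `log`
#'   data frame (epoch, lambda, train loss, validation species accuracy and
#'   macro F1, learning rate), `best_epoch`, and `stopped_early`.
#' @export
train_model <- function(config, data_dir, train_manifest, val_manifest, space) {
  stopifnot(inherits(config, "train_config"))
  n_species <- space$n_species
  if (max(c(train_manifest$species_id, val_manifest$species_id)) >= n_species)
    stop("label space inconsistent with manifests: species index out of range",
         call. = FALSE)
  if (!config$refine) space <- trivial_label_space(n_species)

  targets <- refine_labels(manifest_samples(train_manifest), space)
  model <- build_model(model_config(space$n_refined, config$backbone,
                                    alpha = config$alpha, beta = config$beta),
                       seed = config$seed)

  train_imgs <- load_images(train_manifest, data_dir)
  val_imgs <- load_images(val_manifest, data_dir)
  # evaluation preprocessing is deterministic; do it once
  val_tensors <- lapply(val_imgs, preprocess_eval, input_size = config$input_size)
  val_truth <- val_manifest$species_id

  opt_state <- NULL
  best_acc <- -Inf
  best_params <- model$params
  best_epoch <- 0L
  wait <- 0L
  log <- list()
  stopped_early <- FALSE

  for (t in seq_len(config$max_epochs) - 1L) {
    lam <- lambda_at(t, config$max_epochs, config$lambda_max)
    lr <- if (t < config$warmup_epochs && config$warmup_epochs > 0)
      config$learning_rate * (0.01 + 0.99 * t / config$warmup_epochs)
    else config$learning_rate

    set.seed(epoch_seed(config$seed, t))
    ord <- sample(length(train_imgs))
    losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      gacc <- NULL
      bloss <- 0
      for (ii in idx) {
        xt <- preprocess_train(train_imgs[[ii]], config$input_size)
        fw <- nn_fwd(model, xt)
        probs <- softmax(fw$logits)
        lg <- loss_and_dlogits(probs, targets[ii], lam,
                               config$label_smoothing, config$gamma)
        bloss <- bloss + lg$loss
        g <- nn_bwd(model, fw$cache, lg$dlogits)
        gacc <- if (is.null(gacc)) g else tree_map2(gacc, g, `+`)
      }
      gacc <- tree_map(gacc, function(x) x / length(idx))
      stp <- adamw_step(model$params, gacc, opt_state, lr,
                        config$adam_beta1, config$adam_beta2,
                        weight_decay = config$weight_decay)
      model$params <- stp$params
      opt_state <- stp$state
      losses <- c(losses, bloss / length(idx))
    }

    val_pred <- vapply(val_tensors, function(xt) {
      collapse_predictions(model_probs(model, xt), space, config$collapse_mode)
    }, 0L)
    rep_ <- metrics_report(val_truth, val_pred, n_species)
    log[[length(log) + 1L]] <- data.frame(
      epoch = t, lambda = lam, train_loss = mean(losses),
      val_accuracy = rep_$accuracy, val_macro_f1 = rep_$macro_f1, lr = lr)

    if (rep_$accuracy > best_acc + 1e-12) {
      best_acc <- rep_$accuracy
      best_params <- model$params
      best_epoch <- t
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) {
        stopped_early <- TRUE
        break
      }
    }
  }

  model$params <- best_params
  list(model = model, space = space, log = do.call(rbind, log),
       best_epoch = best_epoch, best_val_accuracy = best_acc,
       stopped_early = stopped_early, config = config)
}

#' Evaluate a model on a manifest
#'
#' Runs deterministic preprocessing and the forward pass, collapses refined
#' predictions to species level, and reports metrics at both label levels
#' (species-level metrics are the headline numbers; refined-level metrics
#' are reported for diagnosis). Optionally writes the species confusion
#' matrix as CSV and the full report as JSON.
#'
#' @param model A trained `pestnet_model` (head sized to `space$n_refined`).
#' @param manifest Evaluation manifest data frame.
#' @param data_dir Dataset directory.
#' @param space The `refined_label_space` used in training.
#' @param input_size Evaluation resolution (use the training `input_size`;
#'   defaults to the shorter side of the first image).
#' @param collapse_mode Collapse rule for species predictions.
#' @param report_dir Optional output directory for `confusion.csv` and
#'   `report.json`.
#' @return List with `species` and `refined` metric reports and the
#'   prediction vectors.
#' @export
evaluate_model <- function(model, manifest, data_dir, space, input_size = NULL,
                           collapse_mode = "argmax_then_map",
                           report_dir = NULL) {
  if (model$config$n_classes != space$n_refined)
    stop(sprintf("model head has %d classes but label space has %d refined classes",
                 model$config$n_classes, space$n_refined), call. = FALSE)
  imgs <- load_images(manifest, data_dir)
  size <- input_size %||% min(dim(imgs[[1]])[1:2])
  probs <- t(vapply(imgs, function(im)
    model_probs(model, preprocess_eval(im, size)), numeric(space$n_refined)))

  refined_pred <- max.col(probs, ties.method = "first") - 1L
  species_pred <- collapse_predictions(probs, space, collapse_mode)
  refined_truth <- refine_labels(manifest_samples(manifest), space)
  species_truth <- manifest$species_id

  species_rep <- metrics_report(species_truth, species_pred, space$n_species)
  refined_rep <- metrics_report(refined_truth, refined_pred, space$n_refined)

  if (!is.null(report_dir)) {
    dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(species_rep$confusion,
                     file.path(report_dir, "confusion.csv"))
    out <- list(species = species_rep[c("accuracy", "macro_f1", "weighted_f1",
                                        "n_samples", "n_correct")],
                refined = refined_rep[c("accuracy", "macro_f1", "weighted_f1")])
    jsonlite::write_json(out, file.path(report_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(species = species_rep, refined = refined_rep,
       species_pred = species_pred, refined_pred = refined_pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a training checkpoint
#'
#' Writes the parameter/config/label-space bundle as an RDS archive plus a
#' human-readable JSON sidecar of the configuration.
#'
#' @param result Result list from [train_model()] (or a list with `model`
#'   and `space`).
#' @param path Checkpoint path (e.g. `best.ckpt`).
#' @export
save_checkpoint <- function(result, path) {
  saveRDS(list(params = result$model$params, config = result$model$config,
               space = unclass(result$space),
               train_config = if (!is.null(result$config)) unclass(result$config)),
          path)
  side <- list(n_classes = result$model$config$n_classes,
               backbone = result$model$config$backbone$variant,
               train_config = if (!is.null(result$config)) unclass(result$config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return List with `model` and `space`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- structure(list(config = obj$config, params = obj$params),
                     class = "pestnet_model")
  sp <- obj$space
  space <- new_label_space(sp$n_species, sp$parent_of, sp$stage_of, sp$min_count)
  tc <- if (!is.null(obj$train_config)) do.call(train_config, obj$train_config)
  list(model = model, space = space, train_config = tc)
}
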