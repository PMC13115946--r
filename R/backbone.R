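# One-shot-aggregation (OSA) backbone.
#
# Each OSA block chains sequential 3x3 convolutions y_i = relu(conv_i(y_{i-1}))
# (y_0 = block input), concatenates the intermediate maps {y_1..y_n} once at
# the block end, and projects the concatenation back to the stage width with a
# 1x1 convolution. The default full-size configuration follows the published
# 57-layer variant: stem 64/64/128 (strides 2/1/2), stages with per-layer
# widths 128/160/192/224, stage outputs 256/512/768/1024, and 1/1/4/3 blocks,
# with 2x2 max-pool downsampling between stages. A 224x224 input therefore
# ends at a 7x7 x 1024 map. Convolutions carry biases; no normalization
# layers are used (the implementation is a deterministic CPU stack).

#' Backbone configuration
#'
#' @param variant `"vovnet57"` (full-size, 5 convolutions per OSA block) or
#'   `"reduced"` (a small stack for desk-scale training and tests).
#' @return List describing stem and stage layouts.
#' @export
backbone_config <- function(variant = c("vovnet57", "reduced")) {
  variant <- match.arg(variant)
  if (variant == "vovnet57") {
    list(variant = variant,
         stem = list(list(in_ch = 3L, out_ch = 64L, stride = 2L),
                     list(in_ch = 64L, out_ch = 64L, stride = 1L),
                     list(in_ch = 64L, out_ch = 128L, stride = 2L)),
         stages = list(
           list(blocks = 1L, layers = 5L, ch = 128L, out = 256L, pool = FALSE),
           list(blocks = 1L, layers = 5L, ch = 160L, out = 512L, pool = TRUE),
           list(blocks = 4L, layers = 5L, ch = 192L, out = 768L, pool = TRUE),
           list(blocks = 3L, layers = 5L, ch = 224L, out = 1024L, pool = TRUE)))
  } else {
    list(variant = variant,
         stem = list(list(in_ch = 3L, out_ch = 8L, stride = 2L),
                     list(in_ch = 8L, out_ch = 16L, stride = 2L)),
         stages = list(
           list(blocks = 1L, layers = 3L, ch = 16L, out = 32L, pool = FALSE),
           list(blocks = 1L, layers = 3L, ch = 24L, out = 64L, pool = TRUE)))
  }
}

#' Full model configuration
#'
#' Assembles the backbone, attention, pooling, and head settings of the
#' classifier. The default spatial-attention hidden width of 50 channels is
#' the calibrated capacity at which the default full model (168 training
#' classes) matches the published 35.65 M parameter budget.
#'
#' @param n_classes Number of output (refined training) classes.
#' @param variant Backbone variant, see [backbone_config()].
#' @param alpha,beta BCSA channel/spatial gains (default 1, symmetric).
#' @param attach_bcsa Attach one BCSA module after every stage (default TRUE).
#' @param ws_hidden Hidden width of the BCSA spatial edge-fusion stack
#'   (default 50 for the full model, 8 for the reduced one).
#' @param gpp_init Initial pooling exponent (GeM convention, 3.0).
#' @param gpp_min Floor of the effective pooling exponent.
#' @return Configuration list consumed by [build_model()].
#' @export
model_config <- function(n_classes, variant = "vovnet57", alpha = 1, beta = 1,
                         attach_bcsa = TRUE, ws_hidden = NULL,
                         gpp_init = 3, gpp_min = 0.5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative", call. = FALSE)
  bb <- backbone_config(variant)
  if (is.null(ws_hidden)) ws_hidden <- if (bb$variant == "vovnet57") 50L else 8L
  list(backbone = bb, n_classes = as.integer(n_classes),
       alpha = alpha, beta = beta, attach_bcsa = isTRUE(attach_bcsa),
       ws_hidden = as.integer(ws_hidden), gpp_init = gpp_init, gpp_min = gpp_min)
}

#' Initialize OSA block parameters
#'
#' @param in_ch Input channel count.
#' @param layer_ch Per-layer channel width.
#' @param out_ch Stage output width (after the 1x1 projection).
#' @param n_layers Number of chained convolutions (5 in the full model).
#' @return List with `convs` (list of w/b pairs) and `proj`.
#' @export
osa_init <- function(in_ch, layer_ch, out_ch, n_layers = 5L) {
  convs <- vector("list", n_layers)
  ic <- in_ch
  for (k in seq_len(n_layers)) {
    convs[[k]] <- init_conv(3L, 3L, ic, layer_ch)
    ic <- layer_ch
  }
  list(convs = convs, proj = init_conv(1L, 1L, n_layers * layer_ch, out_ch))
}

#' OSA block forward pass
#'
#' Sequentially applies the block's rectified convolutions, concatenates all
#' intermediate maps along the channel axis (the concatenation width is the
#' sum of the per-layer widths; the block input is not part of the
#' concatenation), and projects to the stage width with a rectified 1x1
#' convolution. Spatial size is preserved.
#'
#' @param f Input feature map, dim `c(H, W, in_ch)`.
#' @param block Parameters from [osa_init()].
#' @return Output feature map, dim `c(H, W, out_ch)`.
#' @export
osa_forward <- function(f, block) {
  osa_fwd(as_fmap(f), block)$out
}

osa_fwd <- function(x, block) {
  n <- length(block$convs)
  pres <- vector("list", n)
  ys <- vector("list", n)
  y <- x
  for (k in seq_len(n)) {
    pres[[k]] <- conv2d(y, block$convs[[k]]$w, block$convs[[k]]$b)
    y <- relu(pres[[k]])
    ys[[k]] <- y
  }
  hw <- dim(x)[1:2]
  z <- array(unlist(ys, use.names = FALSE),
             dim = c(hw, sum(vapply(ys, function(a) dim(a)[3L], 1L))))
  proj_pre <- conv2d(z, block$proj$w, block$proj$b)
  list(out = relu(proj_pre), x = x, pres = pres, ys = ys, z = z,
       proj_pre = proj_pre)
}

osa_bwd <- function(cache, dout, block) {
  n <- length(block$convs)
  da_p <- dout
  da_p[cache$proj_pre <= 0] <- 0
  bw_p <- conv2d_backward(cache$z, block$proj$w, da_p)
  grads <- list(convs = vector("list", n),
                proj = list(w = bw_p$dw, b = bw_p$db))
  dz <- bw_p$dx
  widths <- vapply(cache$ys, function(a) dim(a)[3L], 1L)
  offs <- cumsum(c(0L, widths))
  dys <- lapply(seq_len(n), function(k) dz[, , (offs[k] + 1L):offs[k + 1L], drop = FALSE])
  dcur <- dys[[n]]
  for (k in n:1) {
    da <- dcur
    da[cache$pres[[k]] <= 0] <- 0
    inp <- if (k == 1L) cache$x else cache$ys[[k - 1L]]
    bw <- conv2d_backward(inp, block$convs[[k]]$w, da)
    grads$convs[[k]] <- list(w = bw$dw, b = bw$db)
    if (k > 1L) dcur <- dys[[k - 1L]] + bw$dx else dx <- bw$dx
  }
  list(dx = dx, grads = grads)
}

#' Build a classifier model
#'
#' Instantiates all learnable parameters (Kaiming-uniform convolutions, zero
#' biases, pooling exponent at its initial value) for the configured
#' backbone + attention + pooling + head.
#'
#' @param config Configuration from [model_config()].
#' @param seed Optional integer seed making initialization reproducible.
#' @return List with `config` and `params`.
#' @export
build_model <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bb <- config$backbone
  params <- list(stem = lapply(bb$stem, function(s)
    init_conv(3L, 3L, s$in_ch, s$out_ch)))
  params$stages <- vector("list", length(bb$stages))
  in_ch <- bb$stem[[length(bb$stem)]]$out_ch
  for (i in seq_along(bb$stages)) {
    st <- bb$stages[[i]]
    blocks <- vector("list", st$blocks)
    bi <- in_ch
    for (j in seq_len(st$blocks)) {
      blocks[[j]] <- osa_init(bi, st$ch, st$out, st$layers)
      bi <- st$out
    }
    stage <- list(blocks = blocks)
    if (config$attach_bcsa)
      stage$bcsa <- bcsa_init(st$out, config$ws_hidden)
    params$stages[[i]] <- stage
    in_ch <- st$out
  }
  params$gpp_p <- config$gpp_init
  params$head <- init_linear(in_ch, config$n_classes)
  structure(list(config = config, params = params), class = "pestnet_model")
}

#' @export
print.pestnet_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("pestnet model (%s backbone, %d classes): %s parameters (%.2f M)\n",
              x$config$backbone$variant, x$config$n_classes,
              format(pc$total, big.mark = ","), pc$millions))
  invisible(x)
}

# flatten nested parameter tree to a named list of leaves ("stem.1.w", ...)
flatten_params <- function(x, prefix = character(0)) {
  if (is.list(x)) {
    out <- list()
    nm <- names(x)
    if (is.null(nm)) nm <- as.character(seq_along(x))
    nm[nm == ""] <- as.character(which(nm == ""))
    for (i in seq_along(x)) {
      key <- if (is.null(names(x)) || names(x)[i] == "") as.character(i) else names(x)[i]
      out <- c(out, flatten_params(x[[i]], c(prefix, key)))
    }
    out
  } else {
    stats::setNames(list(x), paste(prefix, collapse = "."))
  }
}

#' Count trainable parameters
#'
#' Sums every trainable scalar in the model (convolution weights and biases,
#' attention transforms, the pooling exponent, the classifier head). The
#' fixed Sobel kernels carry no parameters.
#'
#' @param model Model from [build_model()].
#' @return List with `total` (raw count) and `millions` (rounded to 2
#'   decimals).
#' @export
count_parameters <- function(model) {
  leaves <- flatten_params(model$params)
  total <- sum(vapply(leaves, length, 1L))
  list(total = total, millions = round(total / 1e6, 2))
}

#' Load pretrained weights by name
#'
#' Copies every archive entry whose name and shape match a model parameter;
#' parameters absent from the archive (for example the attention, pooling,
#' and head weights when loading a backbone-only archive) keep their fresh
#' initialization. A name match with a shape mismatch is an error naming the
#' offending key; nothing is dropped silently.
#'
#' @param archive A named list of arrays, or the path to an RDS file holding
#'   one (flat names as produced by `flatten_params`, e.g. `"stem.1.w"`).
#' @param model Model from [build_model()].
#' @return List with the updated `model` and a `report` listing `loaded`,
#'   `missing`, and `unexpected` key names.
#' @export
load_pretrained <- function(archive, model) {
  if (is.character(archive)) archive <- readRDS(archive)
  if (length(archive) && is.null(names(archive)))
    stop("weight archive must be a named key -> tensor list", call. = FALSE)
  leaves <- flatten_params(model$params)
  loaded <- character(0)
  for (key in intersect(names(archive), names(leaves))) {
    a <- archive[[key]]
    b <- leaves[[key]]
    da <- if (is.null(dim(a))) length(a) else dim(a)
    db <- if (is.null(dim(b))) length(b) else dim(b)
    if (!identical(as.integer(da), as.integer(db)))
      stop(sprintf("shape mismatch for key \"%s\": archive %s vs model %s", key,
                   paste(da, collapse = "x"), paste(db, collapse = "x")),
           call. = FALSE)
    loaded <- c(loaded, key)
  }
  path_assign <- function(tree, path, value) {
    if (length(path) == 1L) {
      tree[[path]] <- value
      return(tree)
    }
    idx <- suppressWarnings(as.integer(path[1L]))
    key <- if (!is.na(idx) && is.null(names(tree))) idx else path[1L]
    tree[[key]] <- path_assign(tree[[key]], path[-1L], value)
    tree
  }
  for (key in loaded) {
    val <- archive[[key]]
    old <- leaves[[key]]
    if (!is.null(dim(old))) dim(val) <- dim(old)
    model$params <- path_assign(model$params, strsplit(key, ".", fixed = TRUE)[[1L]], val)
  }
  report <- list(loaded = loaded,
                 missing = setdiff(names(leaves), names(archive)),
                 unexpected = setdiff(names(archive), names(leaves)))
  list(model = model, report = report)
}

#' Backbone forward pass
#'
#' Runs the stem and all stages on a 3-channel image tensor and returns the
#' ordered per-stage feature maps (post-attention when BCSA is attached).
#' With the full configuration a 3 x 224 x 224 input ends at a 7 x 7 final
#' stage map with 1024 channels.
#'
#' @param model Model from [build_model()].
#' @param image Numeric array dim `c(H, W, 3)`.
#' @return List of per-stage feature maps, one per configured stage.
#' @export
backbone_forward <- function(model, image) {
  image <- as_fmap(image)
  if (dim(image)[3L] != 3L)
    stop(sprintf("backbone expects a 3-channel image, got %d channels",
                 dim(image)[3L]), call. = FALSE)
  nn_fwd(model, image, need_cache = FALSE)$stage_outputs
}
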