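# Whole-network forward/backward. The computation graph is fixed:
#   stem convs (strided) -> [pool?] OSA blocks + BCSA per stage -> GPP -> head
# so backpropagation is hand-chained through the layer caches rather than
# taped. Gradients are exact analytic derivatives; the test suite checks them
# against central finite differences on a tiny configuration.

nn_fwd <- function(model, x, need_cache = TRUE) {
  cfg <- model$config
  p <- model$params
  stem_cache <- list()
  h <- as_fmap(x)
  for (k in seq_along(cfg$backbone$stem)) {
    s <- cfg$backbone$stem[[k]]
    pre <- conv2d(h, p$stem[[k]]$w, p$stem[[k]]$b, stride = s$stride)
    stem_cache[[k]] <- list(x = h, pre = pre)
    h <- relu(pre)
  }
  stage_caches <- vector("list", length(cfg$backbone$stages))
  stage_outputs <- vector("list", length(cfg$backbone$stages))
  for (i in seq_along(cfg$backbone$stages)) {
    st <- cfg$backbone$stages[[i]]
    sc <- list()
    if (st$pool) {
      sc$pool_dims <- dim(h)
      mp <- maxpool2(h)
      sc$pool_idx <- mp$idx
      h <- mp$y
    }
    sc$blocks <- vector("list", st$blocks)
    for (j in seq_len(st$blocks)) {
      bc <- osa_fwd(h, p$stages[[i]]$blocks[[j]])
      sc$blocks[[j]] <- if (need_cache) bc else NULL
      h <- bc$out
    }
    if (cfg$attach_bcsa) {
      ac <- bcsa_fwd(h, p$stages[[i]]$bcsa, cfg$alpha, cfg$beta)
      sc$bcsa <- if (need_cache) ac else NULL
      h <- ac$out
    }
    stage_caches[[i]] <- sc
    stage_outputs[[i]] <- h
  }
  gc_ <- gpp_fwd(h, p$gpp_p, cfg$gpp_min)
  v <- gc_$y
  logits <- as.numeric(t(p$head$w) %*% v + p$head$b)
  list(logits = logits, pooled = v, stage_outputs = stage_outputs,
       cache = if (need_cache) list(stem = stem_cache, stages = stage_caches,
                                    gpp = gc_, pooled = v) else NULL)
}

nn_bwd <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  grads$head <- list(w = outer(cache$pooled, dlogits), b = dlogits)
  dv <- as.numeric(p$head$w %*% dlogits)
  gb <- gpp_bwd(cache$gpp, dv)
  grads$gpp_p <- gb$dp
  dh <- gb$dx
  grads$stages <- vector("list", length(cfg$backbone$stages))
  for (i in rev(seq_along(cfg$backbone$stages))) {
    st <- cfg$backbone$stages[[i]]
    sc <- cache$stages[[i]]
    sg <- list(blocks = vector("list", st$blocks))
    if (cfg$attach_bcsa) {
      ab <- bcsa_bwd(sc$bcsa, dh, p$stages[[i]]$bcsa, cfg$alpha, cfg$beta)
      g <- ab$grads
      sg$bcsa <- list(wc = g$wc, wc_b = g$wc_b,
                      ws = list(w1 = g$ws_w1, b1 = g$ws_b1,
                                w2 = g$ws_w2, b2 = g$ws_b2))
      dh <- ab$dx
    }
    for (j in rev(seq_len(st$blocks))) {
      ob <- osa_bwd(sc$blocks[[j]], dh, p$stages[[i]]$blocks[[j]])
      sg$blocks[[j]] <- ob$grads
      dh <- ob$dx
    }
    if (st$pool) dh <- maxpool2_backward(dh, sc$pool_idx, sc$pool_dims)
    grads$stages[[i]] <- sg
  }
  grads$stem <- vector("list", length(cfg$backbone$stem))
  for (k in rev(seq_along(cfg$backbone$stem))) {
    s <- cfg$backbone$stem[[k]]
    sc <- cache$stem[[k]]
    da <- dh
    da[sc$pre <= 0] <- 0
    bw <- conv2d_backward(sc$x, p$stem[[k]]$w, da, stride = s$stride)
    grads$stem[[k]] <- list(w = bw$dw, b = bw$db)
    dh <- bw$dx
  }
  grads[c("stem", "stages", "gpp_p", "head")]
}

# elementwise combination of two parameter-shaped trees
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else {
    f(a)
  }
}

tree_zero <- function(a) tree_map(a, function(x) x * 0)

# Single-image forward returning softmax probabilities over refined classes.
model_probs <- function(model, image) {
  softmax(nn_fwd(model, image, need_cache = FALSE)$logits)
}

# AdamW step (decoupled weight decay). state holds m, v trees and step t.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  if (is.null(state)) state <- list(m = tree_zero(params), v = tree_zero(params), t = 0L)
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, function(p_, u) p_ - lr * u - lr * weight_decay * p_)
  list(params = params, state = state)
}
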