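# Boundary-aware channel-spatial attention (BCSA).
#
# The module combines two gates applied to a feature map f (H x W x C):
#   * a channel gate g_c = sigmoid(W_c [mu(f), sigma(f)]) built from per-channel
#     mean (global average pooling) and population standard deviation (global
#     standard-deviation pooling) descriptors;
#   * a spatial gate g_s = sigmoid(W_s (E_x + E_y)) built from fixed Sobel edge
#     responses, fused by a small learnable convolution stack;
# and fuses them residually: out = f * (1 + alpha * g_c) * (1 + beta * g_s).

SOBEL_X <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
SOBEL_Y <- t(SOBEL_X)

#' Per-channel spatial statistics (GAP + GSDP)
#'
#' Computes the first- and second-order channel descriptors of a feature map:
#' the spatial mean of each channel (global average pooling) and the spatial
#' population standard deviation (divisor `H*W`, global standard-deviation
#' pooling).
#'
#' @param f Numeric array with dim `c(H, W, C)`.
#' @return A list with numeric vectors `mean` and `std`, each of length `C`.
#' @export
channel_stats <- function(f) {
  f <- as_fmap(f)
  n <- prod(dim(f)[1:2])
  mu <- apply(f, 3L, mean)
  sd <- sqrt(pmax(apply(f, 3L, function(ch) mean((ch - mean(ch))^2)), 0))
  list(mean = mu, std = sd)
}

#' Channel attention gate
#'
#' Applies the learnable transform `W_c` to the concatenated descriptor
#' `[mu(f), sigma(f)]` and squashes with the logistic function, yielding one
#' multiplicative gate per channel, strictly inside (0, 1).
#'
#' @param stats A list with `mean` and `std` vectors (see [channel_stats()]).
#' @param w `C x 2C` weight matrix.
#' @param b Bias vector of length `C`.
#' @return Gate vector `g_c` of length `C`.
#' @export
channel_attention <- function(stats, w, b = NULL) {
  desc <- c(stats$mean, stats$std)
  if (ncol(w) != length(desc))
    stop(sprintf("channel_attention: W_c has %d columns but descriptor length is %d",
                 ncol(w), length(desc)), call. = FALSE)
  if (is.null(b)) b <- numeric(nrow(w))
  as.numeric(logistic(w %*% desc + b))
}

#' Fixed Sobel edge responses
#'
#' Convolves every channel independently (depthwise) with the fixed, non-
#' trainable 3x3 Sobel kernels `S_x = [[-1,0,1],[-2,0,2],[-1,0,1]]` and
#' `S_y = t(S_x)` under zero same-padding. Border pixels carry padding
#' artifacts; interior responses vanish exactly on constant inputs.
#'
#' @param f Numeric array with dim `c(H, W, C)`.
#' @return A list with arrays `ex` and `ey`, each shaped like `f`.
#' @export
sobel_edges <- function(f) {
  f <- as_fmap(f)
  list(ex = depthwise3x3_cpp(f, SOBEL_X), ey = depthwise3x3_cpp(f, SOBEL_Y))
}

#' Spatial attention gate from edge responses
#'
#' Fuses the two Sobel responses by element-wise addition and maps the result
#' through the learnable convolution stack `W_s` (3x3 `C -> hidden`, rectifier,
#' 3x3 `hidden -> 1`) followed by the logistic function.
#'
#' @param edges A list with `ex` and `ey` arrays (see [sobel_edges()]).
#' @param ws A list with fields `w1`, `b1`, `w2`, `b2` (the two convolutions).
#' @return Gate map `g_s` as an `H x W` matrix with entries in (0, 1).
#' @export
spatial_attention <- function(edges, ws) {
  e <- as_fmap(edges$ex) + as_fmap(edges$ey)
  h <- relu(conv2d(e, ws$w1, ws$b1))
  s <- conv2d(h, ws$w2, ws$b2)
  logistic(s[, , 1L])
}

#' Create BCSA parameters for a given channel width
#'
#' @param channels Channel count `C` of the feature map the module attends to.
#' @param hidden Hidden width of the spatial edge-fusion stack.
#' @return Parameter list with `wc` (`C x 2C`), `wc_b`, and the `ws` stack.
#' @export
bcsa_init <- function(channels, hidden = 8L) {
  d <- init_dense(2L * channels, channels)
  c1 <- init_conv(3L, 3L, channels, hidden)
  c2 <- init_conv(3L, 3L, hidden, 1L)
  list(wc = d$w, wc_b = d$b,
       ws = list(w1 = c1$w, b1 = c1$b, w2 = c2$w, b2 = c2$b))
}

#' Boundary-aware channel-spatial attention forward pass
#'
#' Residual multiplicative modulation
#' `out = f * (1 + alpha * g_c) * (1 + beta * g_s)`, with the channel gate
#' broadcast over space and the spatial gate broadcast over channels. At
#' `alpha = beta = 0` the module is the exact identity.
#'
#' @param f Numeric array with dim `c(H, W, C)`.
#' @param params Parameter list from [bcsa_init()].
#' @param alpha,beta Non-negative gains of the channel and spatial gates.
#' @return Modulated feature map, same shape as `f`.
#' @export
bcsa_forward <- function(f, params, alpha = 1, beta = 1) {
  bcsa_fwd(as_fmap(f), params, alpha, beta)$out
}

# internal forward with cache for backprop
bcsa_fwd <- function(f, params, alpha, beta) {
  dims <- dim(f)
  stats <- channel_stats(f)
  desc <- c(stats$mean, stats$std)
  pre_c <- as.numeric(params$wc %*% desc + params$wc_b)
  gc <- logistic(pre_c)

  ex <- depthwise3x3_cpp(f, SOBEL_X)
  ey <- depthwise3x3_cpp(f, SOBEL_Y)
  e <- ex + ey
  h_pre <- conv2d(e, params$ws$w1, params$ws$b1)
  h <- relu(h_pre)
  s_pre <- conv2d(h, params$ws$w2, params$ws$b2)
  gs <- logistic(s_pre[, , 1L])

  A <- 1 + alpha * gc                      # length C
  B <- 1 + beta * gs                       # H x W
  out <- f * rep(A, each = prod(dims[1:2])) * as.numeric(B)
  list(out = out, f = f, stats = stats, desc = desc, gc = gc, gs = gs,
       e = e, h_pre = h_pre, h = h, A = A, B = B)
}

bcsa_bwd <- function(cache, dout, params, alpha, beta) {
  f <- cache$f
  dims <- dim(f)
  hw <- prod(dims[1:2])
  C <- dims[3L]
  Arep <- rep(cache$A, each = hw)
  Brep <- as.numeric(cache$B)

  df <- dout * Arep * Brep
  fB <- f * Brep
  dA <- apply(dout * fB, 3L, sum)                        # length C
  fA <- f * Arep
  dB <- apply(dout * fA, c(1L, 2L), sum)                 # H x W

  grads <- list()

  # channel gate path
  dgc <- alpha * dA
  dpre_c <- dgc * cache$gc * (1 - cache$gc)
  grads$wc <- outer(dpre_c, cache$desc)
  grads$wc_b <- dpre_c
  ddesc <- as.numeric(t(params$wc) %*% dpre_c)
  dmu <- ddesc[seq_len(C)]
  dsd <- ddesc[C + seq_len(C)]
  mu <- cache$stats$mean
  sdv <- pmax(cache$stats$std, 1e-8)
  centered <- f - rep(mu, each = hw)
  df <- df + rep(dmu / hw, each = hw) +
    centered * rep(dsd / (hw * sdv), each = hw)

  # spatial gate path
  dgs <- beta * dB
  ds_pre <- dgs * cache$gs * (1 - cache$gs)
  bw2 <- conv2d_backward(cache$h, params$ws$w2, array(ds_pre, dim = c(dims[1:2], 1L)))
  grads$ws_w2 <- bw2$dw
  grads$ws_b2 <- bw2$db
  dh <- bw2$dx
  dh[cache$h_pre <= 0] <- 0
  bw1 <- conv2d_backward(cache$e, params$ws$w1, dh)
  grads$ws_w1 <- bw1$dw
  grads$ws_b1 <- bw1$db
  de <- bw1$dx
  df <- df + depthwise3x3_cpp(de, rot180(SOBEL_X)) +
    depthwise3x3_cpp(de, rot180(SOBEL_Y))

  list(dx = df, grads = grads)
}
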