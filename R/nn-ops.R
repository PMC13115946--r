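# Low-level tensor primitives. Feature maps are numeric arrays dim c(H, W, C);
# convolution weights are arrays dim c(KH, KW, IC, OC). All convolutions are
# cross-correlations (CNN convention) with zero padding.

as_fmap <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("expected a feature map array with dim c(H, W, C)", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  x <- as_fmap(x)
  dw <- dim(w)
  if (length(dw) != 4L) stop("conv weights must have dim c(KH, KW, IC, OC)", call. = FALSE)
  if (dw[3L] != dim(x)[3L])
    stop(sprintf("conv2d: input has %d channels but weights expect %d",
                 dim(x)[3L], dw[3L]), call. = FALSE)
  if (is.null(pad)) pad <- dw[1L] %/% 2L
  if (is.null(b)) b <- numeric(dw[4L])
  conv2d_fwd_cpp(x, as.numeric(w), as.numeric(b), dw[1L], dw[2L], dw[4L],
                 as.integer(stride), as.integer(pad))
}

conv2d_backward <- function(x, w, dy, stride = 1L, pad = NULL) {
  dw <- dim(w)
  if (is.null(pad)) pad <- dw[1L] %/% 2L
  conv2d_bwd_cpp(as_fmap(x), as.numeric(w), as_fmap(dy),
                 dw[1L], dw[2L], as.integer(stride), as.integer(pad))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

logistic <- function(x) 1 / (1 + exp(-x))

maxpool2 <- function(x) maxpool2_fwd_cpp(as_fmap(x))

maxpool2_backward <- function(dy, idx, dims) {
  maxpool2_bwd_cpp(as_fmap(dy), idx, dims[1L], dims[2L], dims[3L])
}

resize_bilinear <- function(x, oh, ow) {
  resize_bilinear_cpp(as_fmap(x), as.integer(oh), as.integer(ow))
}

rot180 <- function(k) k[nrow(k):1, ncol(k):1, drop = FALSE]

# Kaiming-uniform fan-in initialization (rectifier gain), biases zero.
init_conv <- function(kh, kw, ic, oc) {
  fan_in <- kh * kw * ic
  lim <- sqrt(6 / fan_in)
  list(w = array(stats::runif(kh * kw * ic * oc, -lim, lim), dim = c(kh, kw, ic, oc)),
       b = numeric(oc))
}

init_linear <- function(n_in, n_out) {
  lim <- sqrt(6 / n_in)
  list(w = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

init_dense <- function(n_in, n_out) {
  # n_out x n_in orientation (used by the channel-attention transform W_c)
  lim <- sqrt(6 / n_in)
  list(w = matrix(stats::runif(n_in * n_out, -lim, lim), n_out, n_in),
       b = numeric(n_out))
}
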