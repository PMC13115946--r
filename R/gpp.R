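# Generalized p-norm pooling (GPP): power-mean spatial pooling with a
# learnable sharpness exponent p. At p = 1 it reduces to global average
# pooling; as p grows it approaches per-channel max pooling.

#' Effective pooling exponent
#'
#' The learnable scalar is kept unconstrained and clamped from below at
#' `p_min` when used, so optimization can move freely while the pooling
#' exponent stays in a numerically safe range. The clamp is differentiable
#' almost everywhere (subgradient 0 below the floor).
#'
#' @param raw Unconstrained learnable scalar.
#' @param p_min Floor of the effective exponent (default 0.5, permitting the
#'   smoother-than-average aggregation regime while avoiding the p -> 0
#'   blow-up).
#' @return The effective exponent `max(raw, p_min)`.
#' @export
effective_p <- function(raw, p_min = 0.5) {
  if (!is.finite(raw)) stop("effective_p: raw parameter must be finite", call. = FALSE)
  max(raw, p_min)
}

#' Generalized p-norm pooling
#'
#' Per-channel pooled value `((1/(H*W)) * sum(x^p))^(1/p)` where activations
#' are clamped to at least `eps` before exponentiation (fractional powers of
#' negatives are undefined; the head follows a rectified feature map, so the
#' clamp is inert on positive activations).
#'
#' @param f Numeric array with dim `c(H, W, C)`.
#' @param p Pooling exponent (already on the effective scale, `>= p_min`).
#' @param eps Clamp floor applied before exponentiation.
#' @return Numeric vector of length `C`.
#' @export
gpp_pool <- function(f, p, eps = 1e-6) {
  if (!is.finite(p)) stop("gpp_pool: non-finite pooling exponent", call. = FALSE)
  f <- as_fmap(f)
  x <- pmax(f, eps)
  apply(x, 3L, function(ch) mean(ch^p)^(1 / p))
}

# forward with cache for backprop
gpp_fwd <- function(f, p_raw, p_min = 0.5, eps = 1e-6) {
  p <- effective_p(p_raw, p_min)
  x <- pmax(f, eps)
  hw <- prod(dim(f)[1:2])
  xp <- x^p
  S <- apply(xp, 3L, sum)
  y <- (S / hw)^(1 / p)
  list(y = y, f = f, x = x, xp = xp, S = S, p = p, p_raw = p_raw,
       p_min = p_min, eps = eps, hw = hw)
}

gpp_bwd <- function(cache, dy) {
  p <- cache$p
  hw <- cache$hw
  C <- length(cache$y)
  # dy_c/dx = y^(1-p) * x^(p-1) / hw
  coef <- dy * cache$y^(1 - p) / hw
  dx <- cache$x^(p - 1) * rep(coef, each = hw)
  dx[cache$f < cache$eps] <- 0

  # d y_c / d p = y_c * ( -(1/p^2) log(S/hw) + (1/p) * sum(x^p log x)/S )
  slog <- apply(cache$xp * log(cache$x), 3L, sum)
  dydp <- cache$y * (-log(cache$S / hw) / p^2 + slog / (p * cache$S))
  dp_eff <- sum(dy * dydp)
  dp_raw <- if (cache$p_raw > cache$p_min) dp_eff else 0
  list(dx = dx, dp = dp_raw)
}
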