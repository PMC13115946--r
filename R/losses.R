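# The scheduled mixed objective: label-smoothed cross-entropy blended with
# focal loss under a linearly decaying mixture weight
#   L_total = lambda * L_CE + (1 - lambda) * L_FL,
#   lambda(t) = lambda_max * (1 - t/T).
# Training starts CE-dominated for stability and hands over to the focal term,
# which concentrates gradient on hard (often minority-class) samples.

#' Mixture weight of the scheduled loss
#'
#' Linear decay `lambda_max * (1 - t/T)` over training; `t` is the 0-based
#' epoch counter and `T` the total number of scheduled epochs.
#'
#' @param t Current epoch (0-based), `0 <= t <= T`.
#' @param total_epochs Total scheduled epochs `T >= 1`.
#' @param lambda_max Initial mixture weight in `[0, 1]`.
#' @return The mixture weight `lambda(t)`.
#' @export
lambda_at <- function(t, total_epochs, lambda_max = 1) {
  if (total_epochs < 1) stop("lambda_at: total_epochs must be >= 1", call. = FALSE)
  if (t < 0 || t > total_epochs)
    stop(sprintf("lambda_at: epoch t=%s outside [0, %s]", t, total_epochs), call. = FALSE)
  if (lambda_max < 0 || lambda_max > 1)
    stop("lambda_at: lambda_max must lie in [0, 1]", call. = FALSE)
  lambda_max * (1 - t / total_epochs)
}

check_prob_matrix <- function(probs, tol = 1e-4) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (any(probs < 0)) stop("probabilities must be non-negative", call. = FALSE)
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("probabilities not normalized (max |rowsum - 1| = %.3g)",
                 max(abs(rs - 1))), call. = FALSE)
  probs
}

#' Label-smoothed cross-entropy
#'
#' Cross-entropy of predicted class probabilities against the
#' epsilon-smoothed target distribution: the target class keeps
#' `1 - eps + eps/K` and every class receives `eps/K` (uniform-smoothing
#' convention), averaged over the batch.
#'
#' @param probs Matrix of predicted probabilities (batch x K), rows summing
#'   to 1 within `1e-4`, or a single probability vector.
#' @param target Integer vector of 0-based target class indices.
#' @param epsilon Smoothing mass in `[0, 1)`.
#' @return Mean loss over the batch (non-negative scalar).
#' @export
ce_smoothed <- function(probs, target, epsilon = 0.1) {
  probs <- check_prob_matrix(probs)
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)", call. = FALSE)
  K <- ncol(probs)
  n <- nrow(probs)
  if (length(target) != n) stop("target length must match batch size", call. = FALSE)
  if (any(target < 0 | target >= K)) stop("target class out of range", call. = FALSE)
  lp <- log(pmax(probs, 1e-12))
  pt_lp <- lp[cbind(seq_len(n), target + 1L)]
  mean(-(1 - epsilon) * pt_lp - (epsilon / K) * rowSums(lp))
}

#' Focal loss
#'
#' Per-sample `-(1 - p_t)^gamma * log(p_t)` with `p_t` the probability
#' assigned to the (hard) target class, optionally class-weighted, averaged
#' over the batch. At `gamma = 0` this is exactly plain cross-entropy.
#'
#' @param probs Probability matrix as in [ce_smoothed()].
#' @param target Integer vector of 0-based target class indices.
#' @param gamma Focusing exponent `>= 0`.
#' @param class_weights Optional per-class weight vector of length K.
#' @return Mean loss over the batch.
#' @export
focal <- function(probs, target, gamma = 2, class_weights = NULL) {
  probs <- check_prob_matrix(probs)
  K <- ncol(probs)
  n <- nrow(probs)
  if (length(target) != n) stop("target length must match batch size", call. = FALSE)
  if (any(target < 0 | target >= K)) stop("target class out of range", call. = FALSE)
  if (gamma < 0 || !is.finite(gamma)) stop("gamma must be finite and >= 0", call. = FALSE)
  pt <- pmax(probs[cbind(seq_len(n), target + 1L)], 1e-12)
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[target + 1L]
  mean(-w * (1 - pt)^gamma * log(pt))
}

#' Scheduled total loss
#'
#' `lambda(t) * L_CE + (1 - lambda(t)) * L_FL` with the mixture weight taken
#' from the linear schedule.
#'
#' @param probs Probability matrix as in [ce_smoothed()].
#' @param target Integer vector of 0-based target class indices.
#' @param schedule List with `current_epoch`, `total_epochs`, `lambda_max`.
#' @param epsilon Label-smoothing mass of the CE term.
#' @param gamma Focusing exponent of the focal term.
#' @param class_weights Optional focal class weights.
#' @return Mean total loss over the batch.
#' @export
total_loss <- function(probs, target, schedule, epsilon = 0.1, gamma = 2,
                       class_weights = NULL) {
  lam <- lambda_at(schedule$current_epoch, schedule$total_epochs,
                   schedule$lambda_max)
  lam * ce_smoothed(probs, target, epsilon) +
    (1 - lam) * focal(probs, target, gamma, class_weights)
}

# Per-sample loss and gradient w.r.t. logits, used by the training engine.
# probs = softmax(logits); target is 0-based.
loss_and_dlogits <- function(probs, target, lam, epsilon, gamma) {
  K <- length(probs)
  p <- pmax(probs, 1e-12)
  ti <- target + 1L
  q <- rep(epsilon / K, K)
  q[ti] <- q[ti] + (1 - epsilon)
  l_ce <- -sum(q * log(p))
  pt <- p[ti]
  l_fl <- -(1 - pt)^gamma * log(pt)
  loss <- lam * l_ce + (1 - lam) * l_fl

  dldp <- -lam * q / p
  dfl_dpt <- if (gamma == 0) -1 / pt else
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  dldp[ti] <- dldp[ti] + (1 - lam) * dfl_dpt
  # chain through softmax: dL/dz = p * (dL/dp - sum(p * dL/dp))
  dlogits <- probs * (dldp - sum(probs * dldp))
  list(loss = loss, dlogits = dlogits)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
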