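# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, direct formula expansions,
# and naive convolutions.

# subgroup-counting oracle for the refined label space: returns the expected
# number of refined classes and the per-species split stages
oracle_refined <- function(samples, min_count) {
  stages <- c("Adult", "Larva", "Pupa", "Egg")
  n_species <- max(samples$species) + 1L
  total <- 0L
  split_stages <- vector("list", n_species)
  for (s in 0:(n_species - 1L)) {
    ss <- samples[samples$species == s, , drop = FALSE]
    splits <- character(0)
    for (st in stages) if (sum(ss$stage == st) > min_count) splits <- c(splits, st)
    n_res <- sum(!(ss$stage %in% splits))
    total <- total + length(splits) + as.integer(n_res > 0 || length(splits) == 0)
    split_stages[[s + 1L]] <- splits
  }
  list(n_refined = total, split_stages = split_stages)
}

# naive depthwise 3x3 cross-correlation with zero same-padding
oracle_depthwise3 <- function(x, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, dim(x))
  for (c in seq_len(C)) {
    xp <- matrix(0, H + 2, W + 2)
    xp[2:(H + 1), 2:(W + 1)] <- x[, , c]
    for (i in 1:H) for (j in 1:W)
      y[i, j, c] <- sum(k * xp[i:(i + 2), j:(j + 2)])
  }
  y
}

# two-pass per-channel mean / population sd
oracle_channel_stats <- function(f) {
  C <- dim(f)[3]
  mu <- sd <- numeric(C)
  for (c in seq_len(C)) {
    v <- as.numeric(f[, , c])
    mu[c] <- sum(v) / length(v)
    sd[c] <- sqrt(sum((v - mu[c])^2) / length(v))
  }
  list(mean = mu, std = sd)
}

# exact binomial-sum McNemar oracle
oracle_mcnemar <- function(b, c) {
  n <- b + c
  k <- min(b, c)
  min(1, 2 * sum(choose(n, 0:k)) / 2^n)
}

# random annotated-sample fixture
random_samples <- function(n, n_species, p_unspecified = 0.2) {
  stage <- sample(c("Adult", "Larva", "Pupa", "Egg"), n, replace = TRUE)
  stage[stats::runif(n) < p_unspecified] <- "Unspecified"
  data.frame(image_id = sprintf("img%05d", seq_len(n)),
             species = sample(0:(n_species - 1L), n, replace = TRUE),
             stage = stage, stringsAsFactors = FALSE)
}

# count 4-connected components of a logical matrix (for egg-cluster checks)
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (mask[i0, j0] && lab[i0, j0] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- comp
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- comp
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  comp
}

# multinomial softmax regression on flattened features (plain gradient
# descent, deterministic: zero init, no RNG) -- the "small classifier" used
# to check that synthetic datasets carry learnable signal without involving
# the package's network stack
fit_softmax_clf <- function(X, y, n_classes, iters = 2000, lr = 1) {
  X <- cbind(1, X)
  W <- matrix(0, ncol(X), n_classes)
  n <- nrow(X)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  for (it in seq_len(iters)) {
    Z <- X %*% W
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    W <- W - lr * (t(X) %*% (P - Y) / n + 1e-4 * W)
  }
  W
}

predict_softmax_clf <- function(W, X) max.col(cbind(1, X) %*% W) - 1L

# feature-standardized fit/predict accuracy wrapper
softmax_probe_accuracy <- function(X_tr, y_tr, X_te, y_te, n_classes) {
  mu <- colMeans(X_tr)
  sg <- pmax(apply(X_tr, 2, stats::sd), 1e-6)
  std <- function(X) sweep(sweep(X, 2, mu), 2, sg, "/")
  W <- fit_softmax_clf(std(X_tr), y_tr, n_classes)
  mean(predict_softmax_clf(W, std(X_te)) == y_te)
}

# downsampled RGB features (hue identity -> species signal)
color_features <- function(paths, dir, res = 8) {
  t(vapply(paths, function(p) {
    img <- png::readPNG(file.path(dir, p))[, , 1:3]
    as.numeric(pestnet:::resize_bilinear(img, res, res))
  }, numeric(res * res * 3)))
}

# downsampled RGB plus Sobel edge-magnitude features (shape -> stage signal)
shape_features <- function(paths, dir, res = 10) {
  t(vapply(paths, function(p) {
    img <- png::readPNG(file.path(dir, p))[, , 1:3]
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    e <- sobel_edges(array(gray, c(dim(gray), 1)))
    mag <- array(abs(e$ex) + abs(e$ey), c(dim(gray), 1))
    c(as.numeric(pestnet:::resize_bilinear(img, res, res)),
      as.numeric(pestnet:::resize_bilinear(mag, res, res)))
  }, numeric(res * res * 4)))
}
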