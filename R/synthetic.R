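# Procedural generator of stage-structured insect-scene datasets.
#
# The generator emulates the failure modes of field-collected pest imagery
# that motivate the model: four geometrically distinct stage morphologies per
# species (winged adult / ovoid pupa / segmented larva / egg cluster) sharing
# a species-specific color archetype, cluttered leaf-like backgrounds, partial
# occlusion, illumination jitter, and a long-tailed (power-law) species
# frequency distribution. All randomness flows from one dataset seed with
# per-image sub-seeds derived by counter, so datasets are reproducible.

#' Synthetic dataset specification
#'
#' @param n_species Number of species classes (>= 1).
#' @param n_max Sample count of the most frequent species; species `i`
#'   (1-based rank) receives `max(2, round(n_max * i^-imbalance_exponent))`
#'   samples.
#' @param imbalance_exponent Power-law exponent of the species frequency
#'   distribution; 0 gives balanced classes, the default 1.5 reproduces a
#'   long-tail regime where the largest/smallest class ratio exceeds 5 from
#'   6 species up.
#' @param clutter_level Background texture amplitude in `[0, 1]`; 0 renders
#'   perfectly flat backgrounds.
#' @param occlusion_prob Probability that a foreground band partially
#'   occludes the specimen (at most ~40% of its extent).
#' @param image_size Square image side in pixels (64 by default: fast enough
#'   for CPU training; 224 available for full-scale runs).
#' @param stage_mix Named fractions over
#'   Adult/Larva/Pupa/Egg/Unspecified used to allocate per-species stage
#'   counts (largest-remainder rounding).
#' @param stages_per_species Optional list overriding the automatic
#'   allocation for selected species: element `s + 1` (0-based species `s`),
#'   when non-NULL, is a named integer vector of per-stage counts, e.g.
#'   `c(Adult = 40, Larva = 35)`.
#' @param min_count Split threshold recorded in the generated hierarchy.
#' @param seed Integer master seed.
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(n_species, n_max = 60L, imbalance_exponent = 1.5,
                         clutter_level = 0.6, occlusion_prob = 0.25,
                         image_size = 64L,
                         stage_mix = c(Adult = 0.45, Larva = 0.30, Pupa = 0.10,
                                       Egg = 0.10, Unspecified = 0.05),
                         stages_per_species = NULL, min_count = 30L, seed = 0L) {
  stopifnot(n_species >= 1, n_max >= 2, imbalance_exponent >= 0,
            clutter_level >= 0, clutter_level <= 1,
            occlusion_prob >= 0, occlusion_prob <= 1, image_size >= 16)
  stage_mix <- stage_mix / sum(stage_mix)
  structure(list(n_species = as.integer(n_species), n_max = as.integer(n_max),
                 imbalance_exponent = imbalance_exponent,
                 clutter_level = clutter_level, occlusion_prob = occlusion_prob,
                 image_size = as.integer(image_size), stage_mix = stage_mix,
                 stages_per_species = stages_per_species,
                 min_count = as.integer(min_count), seed = as.integer(seed)),
            class = "dataset_spec")
}

# deterministic species identity: hue / body aspect / stripe frequency
species_archetype <- function(species_id) {
  k <- species_id + 1
  list(species_id = as.integer(species_id),
       hue = (k * 0.6180339887) %% 1,
       aspect = 1.3 + 0.6 * ((k * 0.4142135624) %% 1),
       pattern_freq = 2 + 4 * ((k * 0.7320508076) %% 1))
}

largest_remainder <- function(total, fractions) {
  raw <- total * fractions
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Specimen rendering parameters
#'
#' Draws pose/scale/illumination jitters from the current RNG state and binds
#' them to a species archetype and stage morphology; [render_specimen()] is
#' then fully deterministic given the result.
#'
#' @param archetype Species archetype (internally derived from the species
#'   index).
#' @param stage One of `"Adult"`, `"Larva"`, `"Pupa"`, `"Egg"` (an
#'   unannotated sample still has a true morphology; the generator draws one).
#' @return Parameter list for [render_specimen()].
#' @export
specimen_params <- function(archetype, stage) {
  stage <- match.arg(stage, STAGES)
  list(archetype = archetype, stage = stage,
       angle = stats::runif(1, -0.25, 0.25),
       scale = stats::runif(1, 0.8, 1.1),
       shift = stats::runif(2, -0.1, 0.1),
       illum = stats::runif(1, 0.7, 1.15),
       hue_jitter = stats::runif(1, -0.03, 0.03))
}

#' Render a specimen sprite
#'
#' Draws the stage morphology as an RGBA sprite on a transparent canvas:
#' winged adults (body ellipse plus wing ellipses), ovoid pupae, segmented
#' larvae (a chain of overlapping discs, elongated), and egg clusters (at
#' least three disjoint small discs). Deterministic given its parameters.
#'
#' @param params From [specimen_params()].
#' @param size Canvas side in pixels.
#' @return Numeric array dim `c(size, size, 4)` (RGB + alpha) in `[0, 1]`.
#' @export
render_specimen <- function(params, size = 64L) {
  a <- params$archetype
  g <- seq(-1, 1, length.out = size)
  u0 <- matrix(rep(g, each = size), size, size)        # x coordinate
  v0 <- matrix(rep(g, times = size), size, size)       # y coordinate
  ca <- cos(params$angle); sa <- sin(params$angle)
  u <- ((u0 - params$shift[1]) * ca + (v0 - params$shift[2]) * sa) / params$scale
  v <- (-(u0 - params$shift[1]) * sa + (v0 - params$shift[2]) * ca) / params$scale

  ell <- function(cx, cy, rx, ry) {
    d <- sqrt(((u - cx) / rx)^2 + ((v - cy) / ry)^2)
    pmin(1, pmax(0, (1 - d) * size / 6))
  }
  alpha <- matrix(0, size, size)
  wing <- matrix(0, size, size)
  if (params$stage == "Adult") {
    alpha <- pmax(alpha, ell(0, 0, 0.45, 0.45 / a$aspect))
    wing <- pmax(ell(-0.05, 0.33, 0.33, 0.16), ell(-0.05, -0.33, 0.33, 0.16))
    alpha <- pmax(alpha, wing)
  } else if (params$stage == "Pupa") {
    alpha <- ell(0, 0, 0.34, 0.2)
  } else if (params$stage == "Larva") {
    for (cx in seq(-0.55, 0.55, length.out = 6))
      alpha <- pmax(alpha, ell(cx, 0.08 * sin(3 * cx), 0.14, 0.14))
  } else { # Egg cluster
    eggs <- cbind(c(-0.4, 0, 0.4, -0.2, 0.2, 0), c(-0.3, -0.35, -0.3, 0.1, 0.1, 0.45))
    for (i in seq_len(nrow(eggs)))
      alpha <- pmax(alpha, ell(eggs[i, 1], eggs[i, 2], 0.09, 0.09))
  }

  hue <- (a$hue + params$hue_jitter) %% 1
  val_stage <- c(Adult = 0.85, Larva = 0.75, Pupa = 0.55, Egg = 0.95)[params$stage]
  sat_stage <- c(Adult = 0.75, Larva = 0.85, Pupa = 0.6, Egg = 0.25)[params$stage]
  stripes <- if (params$stage %in% c("Adult", "Larva"))
    0.85 + 0.15 * sin(pi * a$pattern_freq * u) else 1
  base <- grDevices::col2rgb(grDevices::hsv(hue, sat_stage, val_stage)) / 255
  rgb <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) rgb[, , ch] <- base[ch] * stripes
  if (params$stage == "Adult") { # lighten wings relative to body
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] * (1 - 0.5 * wing) + 0.85 * 0.5 * wing
  }
  out <- array(0, dim = c(size, size, 4))
  out[, , 1:3] <- pmin(1, pmax(0, rgb))
  out[, , 4] <- alpha
  out
}

#' Composite a sprite onto a procedural scene
#'
#' Backgrounds are leaf-like superpositions of oriented sinusoid gratings
#' whose amplitude scales with `clutter_level` (flat at 0). With probability
#' `occlusion_prob` a foreground band covering at most ~40% of the specimen
#' extent is drawn over it. Randomness comes from the current RNG state.
#'
#' @param sprite RGBA array from [render_specimen()].
#' @param clutter_level Texture amplitude in `[0, 1]`.
#' @param occlusion_prob Occlusion probability.
#' @param illum Global illumination multiplier.
#' @return RGB array dim `c(size, size, 3)` in `[0, 1]`.
#' @export
render_scene <- function(sprite, clutter_level = 0.5, occlusion_prob = 0,
                         illum = 1) {
  size <- dim(sprite)[1]
  g <- seq(0, 1, length.out = size)
  xx <- matrix(rep(g, each = size), size, size)
  yy <- matrix(rep(g, times = size), size, size)
  base <- c(0.33, 0.42, 0.22)
  tex <- matrix(0, size, size)
  if (clutter_level > 0) {
    for (k in 1:3) {
      th <- stats::runif(1, 0, pi)
      fr <- stats::runif(1, 3, 10)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- c(0.5, 0.3, 0.2)[k]
      tex <- tex + amp * sin(2 * pi * fr * (cos(th) * xx + sin(th) * yy) + ph)
    }
    tex <- clutter_level * 0.35 * tex
  }
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] * (1 + tex)

  al <- sprite[, , 4]
  for (ch in 1:3) img[, , ch] <- (1 - al) * img[, , ch] + al * sprite[, , ch]

  if (stats::runif(1) < occlusion_prob) {
    cols <- which(apply(al > 0.5, 2, any))
    if (length(cols) > 2) {
      bw <- max(1L, floor(0.35 * length(cols)))
      start <- cols[1] + sample.int(max(1L, length(cols) - bw), 1L) - 1L
      band <- start:min(size, start + bw - 1L)
      occ_col <- c(0.45, 0.35, 0.2) * stats::runif(1, 0.8, 1.2)
      for (ch in 1:3) img[, band, ch] <- occ_col[ch]
    }
  }
  img <- img * illum
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic pest-scene dataset
#'
#' Renders every image to `out_dir/images/`, writes a combined manifest plus
#' stratified 60/10/30 train/val/test manifests, and a ground-truth
#' label-space hierarchy built from the training split.
#'
#' @param spec A [dataset_spec()].
#' @param out_dir Output directory (created if needed).
#' @return List with `dir`, the combined `manifest`, the per-split manifests,
#'   and the refined label `space`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "dataset_spec"))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)

  counts <- vapply(seq_len(spec$n_species), function(i)
    max(2L, as.integer(round(spec$n_max * i^(-spec$imbalance_exponent)))), 1L)

  rows <- list()
  counter <- 0L
  for (s in seq_len(spec$n_species) - 1L) {
    arch <- species_archetype(s)
    override <- if (s + 1L <= length(spec$stages_per_species))
      spec$stages_per_species[[s + 1L]]
    if (!is.null(override)) {
      bad <- setdiff(names(override), STAGE_LEVELS)
      if (length(bad)) stop("unknown stage(s) in stages_per_species: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      stage_counts <- stats::setNames(integer(length(STAGE_LEVELS)), STAGE_LEVELS)
      stage_counts[names(override)] <- as.integer(override)
    } else {
      stage_counts <- largest_remainder(counts[s + 1L], spec$stage_mix)
      names(stage_counts) <- names(spec$stage_mix)
    }
    for (st in names(stage_counts)) {
      for (r in seq_len(stage_counts[[st]])) {
        counter <- counter + 1L
        set.seed((spec$seed * 100003L + counter) %% 2147483647L)
        morph <- if (st == "Unspecified") sample(STAGES, 1) else st
        sp <- specimen_params(arch, morph)
        sprite <- render_specimen(sp, spec$image_size)
        clut <- spec$clutter_level * stats::runif(1)^0.5
        img <- render_scene(sprite, clut, spec$occlusion_prob, sp$illum)
        fname <- sprintf("img_%05d_s%02d.png", counter, s)
        png::writePNG(img, file.path(img_dir, fname))
        rows[[counter]] <- data.frame(
          image_path = file.path("images", fname),
          species_id = s, species_name = sprintf("species_%02d", s),
          stage = if (st == "Unspecified") "" else st,
          clutter = round(clut, 6), stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)

  # stratified 60/10/30 split per species, seeded
  set.seed(spec$seed * 7919L %% 2147483647L + 1L)
  manifest$split <- NA_character_
  for (s in seq_len(spec$n_species) - 1L) {
    idx <- sample(which(manifest$species_id == s))
    n <- length(idx)
    n_tr <- max(1L, floor(0.6 * n))
    n_val <- max(1L, floor(0.1 * n))
    if (n_tr + n_val >= n) { n_tr <- max(1L, n - 2L); n_val <- 1L }
    manifest$split[idx[seq_len(n_tr)]] <- "train"
    manifest$split[idx[n_tr + seq_len(n_val)]] <- "val"
    manifest$split[idx[(n_tr + n_val + 1L):n]] <- "test"
  }

  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  for (sp_name in c("train", "val", "test"))
    write_manifest(manifest[manifest$split == sp_name, , drop = FALSE],
                   file.path(out_dir, paste0(sp_name, ".csv")))

  train <- manifest[manifest$split == "train", , drop = FALSE]
  space <- build_refined_label_space(manifest_samples(train), spec$min_count,
                                     n_species = spec$n_species)
  write_hierarchy(space, file.path(out_dir, "hierarchy.json"),
                  names = sprintf("species_%02d", seq_len(spec$n_species) - 1L))

  list(dir = out_dir, manifest = manifest,
       train = train,
       val = manifest[manifest$split == "val", , drop = FALSE],
       test = manifest[manifest$split == "test", , drop = FALSE],
       space = space)
}

#' Select the most cluttered images per class
#'
#' Mirrors the complex-background evaluation protocol: the `k` images with
#' the highest recorded background clutter are selected from every species
#' (ties broken deterministically by image path).
#'
#' @param manifest Manifest data frame with a `clutter` column.
#' @param k_per_class Images to keep per species.
#' @return Subset manifest with `k_per_class` rows per species.
#' @export
complex_background_subset <- function(manifest, k_per_class) {
  if (is.null(manifest$clutter))
    stop("manifest carries no clutter metadata", call. = FALSE)
  if (k_per_class == 0) return(manifest[0, , drop = FALSE])
  out <- list()
  for (s in sort(unique(manifest$species_id))) {
    ms <- manifest[manifest$species_id == s, , drop = FALSE]
    if (nrow(ms) < k_per_class)
      stop(sprintf("species %d has only %d samples (< k = %d)", s, nrow(ms),
                   k_per_class), call. = FALSE)
    ms <- ms[order(-ms$clutter, ms$image_path), , drop = FALSE]
    out[[length(out) + 1L]] <- ms[seq_len(k_per_class), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
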