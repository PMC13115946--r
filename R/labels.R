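# Growth-stage auxiliary label supervision.
#
# Insect species look radically different across developmental stages (adult /
# larva / pupa / egg), which inflates intra-class variance when one species
# label must cover all of them. During training the species label space is
# therefore *refined*: every (species, stage) subgroup with strictly more than
# `min_count` annotated images becomes its own training class; all remaining
# samples of the species (under-threshold stages and samples without a stage
# annotation) share one residual class. At inference, refined predictions are
# collapsed back to species level, so evaluation is always on the original
# species classes.

STAGES <- c("Adult", "Larva", "Pupa", "Egg")
STAGE_LEVELS <- c(STAGES, "Unspecified")

check_samples <- function(samples, n_species = NULL) {
  if (!is.data.frame(samples) || nrow(samples) == 0)
    stop("samples must be a nonempty data frame", call. = FALSE)
  need <- c("image_id", "species", "stage")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  samples$stage <- as.character(samples$stage)
  samples$stage[is.na(samples$stage) | samples$stage == ""] <- "Unspecified"
  bad <- setdiff(unique(samples$stage), STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  samples$species <- as.integer(samples$species)
  if (is.null(n_species)) n_species <- max(samples$species) + 1L
  if (any(samples$species < 0 | samples$species >= n_species))
    stop(sprintf("species index outside [0, %d)", n_species), call. = FALSE)
  attr(samples, "n_species") <- as.integer(n_species)
  samples
}

#' Build a growth-stage refined label space
#'
#' For every (species, stage) subgroup with strictly more than `min_count`
#' annotated samples, a distinct refined training class is created; all
#' remaining samples of a species (under-threshold stages and unannotated
#' samples) share one residual class. A species with no eligible subgroup
#' keeps exactly one (residual) class; a residual class is only created when
#' it would be nonempty, so refined classes never start with zero samples.
#' Refined indices are assigned deterministically: ascending species, stages
#' in the order Adult < Larva < Pupa < Egg, residual class last.
#'
#' @param samples Data frame with columns `image_id`, `species` (0-based
#'   integer), `stage` (one of Adult/Larva/Pupa/Egg/Unspecified; blank or NA
#'   means Unspecified).
#' @param min_count Split threshold: a subgroup is split only when its sample
#'   count is strictly greater than `min_count`.
#' @param n_species Optional total species count (defaults to
#'   `max(species) + 1`).
#' @return An object of class `refined_label_space` with fields `n_species`,
#'   `n_refined`, `parent_of` (0-based, length `n_refined`), `children_of`
#'   (per-species lists of refined indices), `stage_of` (stage name per
#'   refined class, `"residual"` for the catch-all), and `min_count`.
#' @export
build_refined_label_space <- function(samples, min_count = 30L, n_species = NULL) {
  if (min_count < 0) stop("min_count must be >= 0", call. = FALSE)
  samples <- check_samples(samples, n_species)
  n_species <- attr(samples, "n_species")

  parent_of <- integer(0)
  stage_of <- character(0)
  for (s in 0:(n_species - 1L)) {
    ss <- samples[samples$species == s, , drop = FALSE]
    split_stages <- character(0)
    for (st in STAGES) {
      if (sum(ss$stage == st) > min_count) split_stages <- c(split_stages, st)
    }
    n_residual <- sum(!(ss$stage %in% split_stages))
    for (st in split_stages) {
      parent_of <- c(parent_of, s)
      stage_of <- c(stage_of, st)
    }
    if (n_residual > 0 || length(split_stages) == 0) {
      parent_of <- c(parent_of, s)
      stage_of <- c(stage_of, "residual")
    }
  }
  new_label_space(n_species, parent_of, stage_of, as.integer(min_count))
}

new_label_space <- function(n_species, parent_of, stage_of, min_count) {
  n_refined <- length(parent_of)
  children_of <- lapply(0:(n_species - 1L),
                        function(s) which(parent_of == s) - 1L)
  if (any(vapply(children_of, length, 1L) == 0))
    stop("label space invalid: species without refined children", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 n_refined = as.integer(n_refined),
                 parent_of = as.integer(parent_of),
                 children_of = children_of,
                 stage_of = as.character(stage_of),
                 min_count = as.integer(min_count)),
            class = "refined_label_space")
}

#' @export
print.refined_label_space <- function(x, ...) {
  n_split <- sum(x$stage_of != "residual")
  cat(sprintf("Refined label space: %d species -> %d training classes\n",
              x$n_species, x$n_refined))
  cat(sprintf("  %d stage-specific classes (threshold: > %d images), %d residual classes\n",
              n_split, x$min_count, sum(x$stage_of == "residual")))
  invisible(x)
}

#' Map samples to refined training labels
#'
#' Each sample maps to its stage-specific class when that (species, stage)
#' subgroup was split, otherwise to the residual class of its species. By
#' construction `parent_of[refine_labels(s)] == s$species`.
#'
#' @param samples Data frame as in [build_refined_label_space()].
#' @param space A `refined_label_space`, built from a superset of these
#'   samples' species.
#' @return Integer vector of 0-based refined class indices.
#' @export
refine_labels <- function(samples, space) {
  samples <- check_samples(samples, space$n_species)
  out <- integer(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples$species[i]
    kids <- space$children_of[[s + 1L]]
    stages <- space$stage_of[kids + 1L]
    hit <- kids[stages == samples$stage[i]]
    if (length(hit) == 1L) {
      out[i] <- hit
    } else {
      res <- kids[stages == "residual"]
      if (length(res) != 1L)
        stop(sprintf("species %d has no residual class for stage %s",
                     s, samples$stage[i]), call. = FALSE)
      out[i] <- res
    }
  }
  out
}

#' Collapse refined predictions to species level
#'
#' Either maps the refined argmax through `parent_of` (`argmax_then_map`,
#' the default) or first sums child probabilities per species and takes the
#' species argmax (`sum_probs`). Ties break toward the lowest class index.
#'
#' @param scores Numeric vector of per-refined-class scores (length
#'   `n_refined`, entries >= 0), or a matrix with one row per sample.
#' @param space A `refined_label_space`.
#' @param mode `"argmax_then_map"` or `"sum_probs"`.
#' @return 0-based species index (vector if `scores` is a matrix).
#' @export
collapse_predictions <- function(scores, space,
                                 mode = c("argmax_then_map", "sum_probs")) {
  mode <- match.arg(mode)
  if (is.matrix(scores)) {
    return(vapply(seq_len(nrow(scores)),
                  function(i) collapse_predictions(scores[i, ], space, mode), 0L))
  }
  if (length(scores) != space$n_refined)
    stop(sprintf("scores length %d but label space has %d refined classes",
                 length(scores), space$n_refined), call. = FALSE)
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  if (mode == "argmax_then_map") {
    space$parent_of[which.max(scores)]
  } else {
    per_species <- vapply(space$children_of,
                          function(kids) sum(scores[kids + 1L]), 0)
    which.max(per_species) - 1L
  }
}

#' Write a refined label space to JSON
#'
#' @param space A `refined_label_space`.
#' @param path Output path.
#' @param names Optional character vector of species names, stored alongside.
#' @export
write_hierarchy <- function(space, path, names = NULL) {
  obj <- list(n_species = space$n_species,
              n_refined = space$n_refined,
              min_count = space$min_count,
              parent_of = space$parent_of,
              stage_of = space$stage_of)
  if (!is.null(names)) obj$names <- as.character(names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a refined label space from JSON
#'
#' @param path Path to a hierarchy file written by [write_hierarchy()].
#' @return A `refined_label_space`; parse errors name the offending key.
#' @export
read_hierarchy <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("hierarchy file is not valid JSON: ",
                                           conditionMessage(e), call. = FALSE))
  for (key in c("n_species", "n_refined", "min_count", "parent_of", "stage_of")) {
    if (is.null(obj[[key]]))
      stop(sprintf("hierarchy file missing required key \"%s\"", key), call. = FALSE)
  }
  if (length(obj$parent_of) != obj$n_refined)
    stop("hierarchy file: \"parent_of\" length disagrees with \"n_refined\"", call. = FALSE)
  sp <- new_label_space(obj$n_species, obj$parent_of, obj$stage_of, obj$min_count)
  if (!is.null(obj$names)) attr(sp, "names_species") <- obj$names
  sp
}

#' Read a dataset manifest CSV
#'
#' Manifests carry at least `image_path`, `species_id`, `species_name`,
#' `stage` (blank stage means no annotation); generator manifests add `split`
#' and `clutter` columns.
#'
#' @param path Path to the CSV.
#' @return Data frame with a blank-stage column normalized to "Unspecified".
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stage = "character"))
  need <- c("image_path", "species_id", "species_name", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df$stage[is.na(df$stage) | df$stage == ""] <- "Unspecified"
  df
}

#' Write a dataset manifest CSV
#'
#' @param df Manifest data frame.
#' @param path Output path.
#' @export
write_manifest <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a manifest to annotated samples
#'
#' @param manifest Data frame from [read_manifest()].
#' @return Data frame with `image_id`, `species`, `stage` columns as consumed
#'   by [build_refined_label_space()] and [refine_labels()].
#' @export
manifest_samples <- function(manifest) {
  data.frame(image_id = manifest$image_path,
             species = as.integer(manifest$species_id),
             stage = manifest$stage,
             stringsAsFactors = FALSE)
}
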