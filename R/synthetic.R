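# Synthetic fundus generator.
#
# A test instrument, not a clinical simulator: it emulates the two
# properties the pipeline needs from real data — (1) dark branching vessel
# trees of decreasing caliber on a bright circular fundus field, paired
# with exact rasterised masks, and (2) grade-dependent lesion content
# (dark microaneurysm-like dots and bright exudate-like blobs whose
# expected count rises with grade 0 -> 4).  Contrast and lesion rates are
# deliberately strong so that tiny CPU-scale networks can learn both
# tasks in minutes.  All randomness flows through seeds derived from
# (seed, index, grade); regeneration is byte-identical.

#' Synthetic fundus configuration
#'
#' @param size Image side length in pixels.
#' @param n_images Number of images a dataset generation produces.
#' @param seed Master seed; every image is a pure function of
#'   `(seed, index)` (plus `grade` for lesion images).
#' @param depth Branching depth of the vessel tree (levels of bifurcation).
#' @param initial_width Trunk caliber in pixels.
#' @param width_decay Caliber multiplier per branching, in (0, 1).
#' @param lesion_rates Five nondecreasing per-grade mean lesion counts
#'   (Poisson rates for the dark dots; bright blobs use half the rate).
#' @param noise_sigma Gaussian pixel noise added after rasterisation.
#' @param vessel_contrast How much darker (pre-noise) a vessel pixel is
#'   than the local background, in [0, 1] intensity units.
#' @return A `ret_synth_config`.
#' @export
synth_config <- function(size = 128L, n_images = 20L, seed = 0L,
                         depth = 5L, initial_width = 6,
                         width_decay = 0.85,
                         lesion_rates = c(0, 4, 10, 18, 30),
                         noise_sigma = 0.02, vessel_contrast = 0.45) {
  stopifnot(size >= 32, n_images >= 1, depth >= 0, initial_width > 0)
  if (width_decay <= 0 || width_decay >= 1) {
    stop("width_decay must lie in (0, 1)")
  }
  if (length(lesion_rates) != 5L || any(diff(lesion_rates) < 0)) {
    stop("lesion_rates must be 5 nondecreasing per-grade rates")
  }
  structure(list(size = as.integer(size), n_images = as.integer(n_images),
                 seed = as.integer(seed), depth = as.integer(depth),
                 initial_width = initial_width, width_decay = width_decay,
                 lesion_rates = lesion_rates, noise_sigma = noise_sigma,
                 vessel_contrast = vessel_contrast),
            class = "ret_synth_config")
}

mix_seed <- function(seed, index, grade = 0L) {
  ((seed %% 100000L) * 10007L + index * 101L + grade * 13L + 17L) %%
    2147483647L
}

disk_offsets_env <- new.env(parent = emptyenv())

disk_offsets <- function(radius) {
  key <- sprintf("%.2f", radius)
  hit <- disk_offsets_env[[key]]
  if (!is.null(hit)) return(hit)
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  disk_offsets_env[[key]] <- g
  g
}

stamp_disk <- function(mask, cy, cx, radius) {
  off <- disk_offsets(max(radius, 0.5))
  ys <- round(cy) + off$dy
  xs <- round(cx) + off$dx
  keep <- ys >= 1 & ys <= nrow(mask) & xs >= 1 & xs <= ncol(mask)
  mask[cbind(ys[keep], xs[keep])] <- 1L
  mask
}

# Recursive random-walk binary branching tree rasterised onto a 0/1 grid.
draw_tree <- function(size, depth, width0, decay) {
  mask <- matrix(0L, size, size)
  if (depth <= 0L) return(mask)   # zero-depth tree draws nothing
  centre <- (size + 1) / 2
  field_r <- 0.47 * size
  branch <- function(y, x, angle, width, level) {
    if (level < 0L || width < 0.7) return()
    len <- stats::runif(1, 0.16, 0.26) * size
    for (s in seq_len(round(len))) {
      angle <- angle + stats::rnorm(1, 0, 0.07)
      y <- y + sin(angle)
      x <- x + cos(angle)
      if ((y - centre)^2 + (x - centre)^2 > field_r^2) return()
      mask <<- stamp_disk(mask, y, x, width / 2)
    }
    spread <- stats::runif(1, 0.35, 0.75)
    branch(y, x, angle - spread, width * decay, level - 1L)
    branch(y, x, angle + spread, width * decay, level - 1L)
  }
  # two trunks leaving the disc centre region in opposed directions,
  # like the superior/inferior vascular arcades
  a0 <- stats::runif(1, 0, 2 * pi)
  for (a in c(a0, a0 + pi + stats::rnorm(1, 0, 0.3))) {
    branch(centre + stats::rnorm(1, 0, size / 20),
           centre + stats::rnorm(1, 0, size / 20),
           a, width0, depth)
  }
  mask
}

fundus_field <- function(size) {
  centre <- (size + 1) / 2
  field_r <- 0.47 * size
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  r2 <- ((yy - centre)^2 + (xx - centre)^2) / field_r^2
  inside <- r2 <= 1
  base <- ifelse(inside, 0.88 - 0.18 * r2, 0.03)
  list(base = base, inside = inside)
}

# fundus-like colour: strong red, medium green, weak blue
FUNDUS_TINT <- c(1.0, 0.72, 0.45)

render_fundus <- function(base, mask, contrast, sigma) {
  size <- nrow(base)
  img <- array(0, c(size, size, 3L))
  lum <- base - contrast * mask
  for (c in 1:3) {
    ch <- lum * FUNDUS_TINT[c]
    if (sigma > 0) ch <- ch + stats::rnorm(length(ch), 0, sigma)
    img[, , c] <- pmin(pmax(ch, 0), 1)
  }
  img
}

#' Generate one synthetic vessel image with its exact mask
#'
#' Fully determined by `(cfg$seed, index)`: a bright circular fundus field
#' on a dark surround, a recursive binary branching vessel tree with
#' random-walk curvature and caliber decaying per bifurcation, rasterised
#' exactly into the mask; the image draws the tree `vessel_contrast`
#' darker than the background and adds Gaussian noise (the mask is
#' pre-noise, hence exact).
#'
#' @param cfg A [synth_config()].
#' @param index Image index (1-based).
#' @return List `image` (`[size, size, 3]` in `[0, 1]`) and `mask`
#'   (`[size, size]` 0/1).
#' @export
generate_vessel_pair <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "ret_synth_config"))
  set.seed(mix_seed(cfg$seed, index))
  mask <- draw_tree(cfg$size, cfg$depth, cfg$initial_width,
                    cfg$width_decay)
  fld <- fundus_field(cfg$size)
  mask[!fld$inside] <- 0L
  img <- render_fundus(fld$base, mask, cfg$vessel_contrast,
                       cfg$noise_sigma)
  list(image = img, mask = mask)
}

stamp_lesions <- function(lum, inside, n, radius_range, delta) {
  size <- nrow(lum)
  centre <- (size + 1) / 2
  field_r <- 0.47 * size
  for (i in seq_len(n)) {
    repeat {
      y <- stats::runif(1, 1, size)
      x <- stats::runif(1, 1, size)
      if ((y - centre)^2 + (x - centre)^2 <= (0.85 * field_r)^2) break
    }
    r <- stats::runif(1, radius_range[1], radius_range[2])
    off <- disk_offsets(r)
    ys <- round(y) + off$dy
    xs <- round(x) + off$dx
    keep <- ys >= 1 & ys <= size & xs >= 1 & xs <= size
    lum[cbind(ys[keep], xs[keep])] <- lum[cbind(ys[keep], xs[keep])] + delta
  }
  lum
}

#' Generate one synthetic graded retinopathy image
#'
#' A vessel background plus `Poisson(lesion_rates[grade + 1])` dark
#' microaneurysm-like dots and `Poisson(rate / 2)` bright exudate-like
#' blobs; fully determined by `(cfg$seed, grade, index)`.
#'
#' @param cfg A [synth_config()].
#' @param grade Integer grade 0..4.
#' @param index Image index.
#' @return List `image`, `grade`, and the underlying vessel `mask` (so
#'   jointly-labelled records are possible).
#' @export
generate_dr_image <- function(cfg, grade, index = 1L) {
  stopifnot(inherits(cfg, "ret_synth_config"))
  check_grades(grade)
  set.seed(mix_seed(cfg$seed, index, grade + 1L))
  mask <- draw_tree(cfg$size, cfg$depth, cfg$initial_width,
                    cfg$width_decay)
  fld <- fundus_field(cfg$size)
  mask[!fld$inside] <- 0L
  rate <- cfg$lesion_rates[grade + 1L]
  lum <- fld$base - cfg$vessel_contrast * mask
  n_dots <- stats::rpois(1, rate)
  n_blobs <- stats::rpois(1, rate / 2)
  lum <- stamp_lesions(lum, fld$inside, n_dots, c(1.2, 2.2), -0.38)
  lum <- stamp_lesions(lum, fld$inside, n_blobs, c(2.0, 3.5), +0.30)
  img <- array(0, c(cfg$size, cfg$size, 3L))
  for (c in 1:3) {
    ch <- lum * FUNDUS_TINT[c]
    if (cfg$noise_sigma > 0) {
      ch <- ch + stats::rnorm(length(ch), 0, cfg$noise_sigma)
    }
    img[, , c] <- pmin(pmax(ch, 0), 1)
  }
  list(image = img, grade = as.integer(grade), mask = mask)
}

# APTOS-style class imbalance (normal, mild, moderate, severe,
# proliferative)
DR_CLASS_WEIGHTS <- c(1805, 370, 999, 193, 295)

#' Apportion n images over the five grades (largest remainder)
#'
#' Follows the canonical APTOS class imbalance 1805:370:999:193:295 by
#' default; the largest-remainder rule makes the histogram sum exactly to
#' `n`.
#'
#' @param n Total images.
#' @param weights Five non-negative class weights.
#' @return Integer vector of 5 counts summing to `n`.
#' @export
apportion_grades <- function(n, weights = DR_CLASS_WEIGHTS) {
  stopifnot(length(weights) == 5L, all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

#' Generate a synthetic dataset (in memory, optionally on disk)
#'
#' `kind = "vessel"` produces image/mask pairs; `"dr"` produces graded
#' images with the APTOS-style grade histogram (largest-remainder
#' apportionment); `"joint"` produces records carrying both a mask and a
#' grade.  With `dir` given, images are written as ASCII PPM, masks as
#' ASCII PGM, plus `grades.csv` (id_code/diagnosis) for graded kinds and
#' `manifest.csv`; regeneration with the same config is byte-identical.
#'
#' @param cfg A [synth_config()].
#' @param kind `"vessel"`, `"dr"` or `"joint"`.
#' @param dir Optional output directory (created if needed).
#' @return A `ret_dataset`; when `dir` is given, with the manifest path in
#'   attribute `"manifest"`.
#' @export
generate_dataset <- function(cfg, kind = c("vessel", "dr", "joint"),
                             dir = NULL) {
  kind <- match.arg(kind)
  n <- cfg$n_images
  grades <- NULL
  if (kind != "vessel") {
    counts <- apportion_grades(n)
    grades <- rep(0:4, counts)
  }
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    r <- if (kind == "vessel") generate_vessel_pair(cfg, i)
         else generate_dr_image(cfg, grades[i], i)
    images[[i]] <- r$image
    masks[[i]] <- r$mask
  }
  ids <- sprintf("syn_%s_%03d", kind, seq_len(n))
  keep_masks <- kind != "dr"
  data <- ret_dataset(images = images,
                      masks = if (keep_masks) masks,
                      grades = grades, ids = ids)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
      stop("cannot create output directory: ", dir)
    }
    # manifest paths are relative to the dataset directory so that
    # regeneration into any directory is byte-identical
    img_paths <- paste0(ids, ".ppm")
    mask_paths <- if (keep_masks) paste0(ids, "_mask.pgm")
    for (i in seq_len(n)) {
      write_pnm(images[[i]], file.path(dir, img_paths[i]))
      if (keep_masks) write_mask(masks[[i]], file.path(dir, mask_paths[i]))
    }
    if (!is.null(grades)) {
      utils::write.csv(data.frame(id_code = ids, diagnosis = grades),
                       file.path(dir, "grades.csv"), row.names = FALSE)
    }
    mf <- as_manifest(data.frame(
      id = ids, image = img_paths,
      mask = if (keep_masks) mask_paths else NA_character_,
      grade = if (is.null(grades)) NA_integer_ else grades,
      split = NA_character_, stringsAsFactors = FALSE),
      source = "retinet synthetic generator")
    write_manifest(mf, file.path(dir, "manifest.csv"))
    attr(data, "manifest") <- file.path(dir, "manifest.csv")
  }
  data
}
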