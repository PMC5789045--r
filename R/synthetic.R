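#' Configuration of the phantom-radiograph generator
#'
#' The generator renders a stylised anteroposterior knee: two horizontal
#' cortical "bone" bands (distal femur above, proximal tibia below)
#' separated by a radiolucent joint space, on a soft-tissue background.
#' Grade severity is encoded through the three radiological KL features the
#' grading method relies on: the joint space narrows with grade, marginal
#' osteophytes (bright blobs at the lateral/medial joint corners) grow with
#' grade, and the subchondral bands immediately adjacent to the joint
#' brighten with grade (sclerosis). Each phantom additionally receives a
#' random joint-line tilt, a random vertical shift, Gaussian pixel noise
#' and a global intensity offset, so adjacent grades overlap and the
#' learning task is noisy but solvable — a caricature of radiographic OA,
#' not an anatomical simulation.
#'
#' @param image_px square image side in pixels (default 280; with the
#'   default spacing this is the 140 mm ROI the pipeline expects).
#' @param spacing_mm pixel spacing (default 0.5 mm/px).
#' @param joint_space_mm mean joint-space width per grade 0..4, strictly
#'   decreasing.
#' @param gap_sd_mm per-phantom standard deviation of the drawn gap width.
#' @param osteophyte_amp per-grade osteophyte amplitude (relative to bone
#'   intensity), non-decreasing.
#' @param sclerosis_gain per-grade relative brightening of the subchondral
#'   bands.
#' @param noise_sd Gaussian pixel noise, 16-bit intensity units.
#' @param tilt_deg maximum joint-line tilt in degrees.
#' @param shift_px maximum vertical shift of the joint line.
#' @param offset_range half-width of the uniform global intensity offset.
#' @param bone_level,background base 16-bit intensities.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_px = 280L, spacing_mm = 0.5,
                           joint_space_mm = c(6, 5, 4, 2.5, 1),
                           gap_sd_mm = 0.35,
                           osteophyte_amp = c(0, 0.1, 0.25, 0.5, 0.8),
                           sclerosis_gain = c(0, 0.05, 0.12, 0.2, 0.3),
                           noise_sd = 800, tilt_deg = 1.5, shift_px = 5,
                           offset_range = 1500,
                           bone_level = 30000, background = 8000) {
  if (any(diff(joint_space_mm) >= 0))
    stop("`joint_space_mm` must be strictly decreasing over grades 0..4")
  if (any(diff(osteophyte_amp) < 0))
    stop("`osteophyte_amp` must be non-decreasing over grades")
  structure(list(image_px = as.integer(image_px), spacing_mm = spacing_mm,
                 joint_space_mm = joint_space_mm, gap_sd_mm = gap_sd_mm,
                 osteophyte_amp = osteophyte_amp,
                 sclerosis_gain = sclerosis_gain, noise_sd = noise_sd,
                 tilt_deg = tilt_deg, shift_px = shift_px,
                 offset_range = offset_range, bone_level = bone_level,
                 background = background),
            class = "phantom_config")
}

#' Render one phantom knee radiograph
#'
#' @param grade KL grade 0..4 of the phantom.
#' @param cfg a [phantom_config()].
#' @param seed RNG seed; the same seed reproduces the phantom exactly.
#' @return A [knee_roi()] with `kl_grade` set and two attributes:
#'   `margin_mask`, a logical matrix marking the joint-margin region
#'   (osteophyte and subchondral zone at the lateral/medial thirds) used by
#'   attention-localisation tests, and `gap_mm`, the drawn joint-space
#'   width.
#' @export
make_phantom <- function(grade, cfg = phantom_config(), seed = 1L) {
  if (!grade %in% 0:4) stop("`grade` must be in 0..4")
  set.seed(seed)
  g <- grade + 1L
  n <- cfg$image_px
  sp <- cfg$spacing_mm

  gap_mm <- max(0.4, cfg$joint_space_mm[g] + stats::rnorm(1, 0, cfg$gap_sd_mm))
  gap_px <- gap_mm / sp
  c0 <- n / 2 + stats::runif(1, -cfg$shift_px, cfg$shift_px)
  slope <- tan(stats::runif(1, -cfg$tilt_deg, cfg$tilt_deg) * pi / 180)

  xs <- seq_len(n)
  center <- c0 + slope * (xs - n / 2)          # joint-line row per column
  gap_top <- center - gap_px / 2
  gap_bot <- center + gap_px / 2
  bone_h <- 0.32 * n
  femur_top <- center - bone_h
  tibia_bot <- center + bone_h

  R <- matrix(seq_len(n), n, n)                # row index of each pixel
  GT <- matrix(gap_top, n, n, byrow = TRUE)
  GB <- matrix(gap_bot, n, n, byrow = TRUE)
  FT <- matrix(femur_top, n, n, byrow = TRUE)
  TB <- matrix(tibia_bot, n, n, byrow = TRUE)

  img <- matrix(cfg$background, n, n)
  in_femur <- R >= FT & R <= GT
  in_tibia <- R >= GB & R <= TB
  img[in_femur | in_tibia] <- cfg$bone_level

  band_px <- 4 / sp                            # 4 mm subchondral band
  sub <- (in_femur & R >= GT - band_px) | (in_tibia & R <= GB + band_px)
  img[sub] <- img[sub] * (1 + cfg$sclerosis_gain[g])

  amp <- cfg$osteophyte_amp[g]
  if (amp > 0) {
    Cx <- matrix(xs, n, n, byrow = TRUE)
    sigma <- 4 / sp * 0.5                      # ~2 mm blobs
    for (mx in c(0.10 * n, 0.90 * n)) {
      cx <- mx + stats::runif(1, -3, 3)
      cy_t <- stats::approx(xs, gap_top, xout = cx)$y
      cy_b <- stats::approx(xs, gap_bot, xout = cx)$y
      for (cy in c(cy_t, cy_b)) {
        blob <- exp(-((Cx - cx)^2 + (R - cy)^2) / (2 * sigma^2))
        img <- img + amp * cfg$bone_level * blob
      }
    }
  }

  img <- img + stats::rnorm(n * n, 0, cfg$noise_sd) +
    stats::runif(1, -cfg$offset_range, cfg$offset_range)
  img <- round(pmin(pmax(img, 0), 65535))

  margin_cols <- matrix(xs, n, n, byrow = TRUE)
  mask <- (margin_cols <= 0.22 * n | margin_cols >= 0.78 * n) &
    R >= GT - band_px - 4 & R <= GB + band_px + 4

  roi <- knee_roi(img, spacing_mm = sp, side = "right",
                  kl_grade = grade,
                  source_id = sprintf("phantom_g%d_s%d", grade, seed))
  attr(roi, "margin_mask") <- mask
  attr(roi, "gap_mm") <- gap_mm
  roi
}

#' Measure the joint-space width of a phantom
#'
#' Hand-crafted reference measurement used to check grade separability:
#' the intensity profile averaged over the central columns is thresholded
#' halfway between background and bone, and the radiolucent run nearest the
#' image centre is counted.
#'
#' @param roi a [knee_roi()] phantom.
#' @return Estimated joint-space width in millimetres.
#' @export
measure_joint_space <- function(roi) {
  px <- roi$pixels
  n <- nrow(px)
  cols <- max(1, round(n / 2) - 10):min(n, round(n / 2) + 10)
  prof <- rowMeans(px[, cols, drop = FALSE])
  thr <- (max(prof) + min(prof)) / 2
  dark <- prof < thr
  runs <- rle(dark)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  gaps <- which(runs$values)
  if (!length(gaps)) return(NA_real_)
  mid <- n / 2
  # radiolucent run whose span is nearest the image centre
  d <- vapply(gaps, function(k) {
    if (mid >= starts[k] && mid <= ends[k]) 0
    else min(abs(c(starts[k], ends[k]) - mid))
  }, numeric(1))
  k <- gaps[which.min(d)]
  runs$lengths[k] * roi$spacing_mm
}

#' Generate a balanced labelled phantom dataset
#'
#' Renders `n_per_grade` phantoms for each KL grade with per-phantom seeds
#' drawn from the master seed, and assigns train/validation/test splits
#' stratified by grade (phantom ids are disjoint across splits).
#'
#' @param n_per_grade phantoms per grade (>= 1).
#' @param cfg a [phantom_config()].
#' @param seed master seed; the same seed reproduces the whole dataset.
#' @param split train/validation/test fractions summing to 1.
#' @return A list with `rois` (list of [knee_roi()]) and `manifest`
#'   (data.frame with `id`, `grade`, `seed`, `split`).
#' @export
make_dataset <- function(n_per_grade, cfg = phantom_config(), seed = 7L,
                         split = c(train = 0.6, val = 0.2, test = 0.2)) {
  stopifnot(n_per_grade >= 1, abs(sum(split) - 1) < 1e-8)
  set.seed(seed)
  n_tot <- 5L * n_per_grade
  seeds <- sample.int(.Machine$integer.max, n_tot)
  grades <- rep(0:4, each = n_per_grade)
  split_of <- function(i) {
    # position within its grade block, split by cumulative fractions
    k <- (i - 1L) %% n_per_grade + 1L
    cuts <- round(cumsum(split) * n_per_grade)
    if (k <= cuts[1]) "train" else if (k <= cuts[2]) "val" else "test"
  }
  manifest <- data.frame(
    id = sprintf("ph%04d", seq_len(n_tot)),
    grade = grades,
    seed = seeds,
    split = vapply(seq_len(n_tot), split_of, character(1)),
    stringsAsFactors = FALSE
  )
  rois <- lapply(seq_len(n_tot), function(i) {
    r <- make_phantom(grades[i], cfg, seed = seeds[i])
    r$source_id <- manifest$id[i]
    r
  })
  list(rois = rois, manifest = manifest)
}

#' Run-length encode a logical mask
#'
#' Storage format for feature-mask sidecars: the mask is flattened in
#' column-major order and stored as alternating run lengths starting with
#' a `FALSE` run.
#'
#' @param mask logical matrix.
#' @return List with `dim` and integer `runs`.
#' @export
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  runs <- r$lengths
  if (r$values[1]) runs <- c(0L, runs)
  list(dim = dim(mask), runs = as.integer(runs))
}

#' @rdname mask_to_rle
#' @param rle a list as returned by `mask_to_rle()`.
#' @export
rle_to_mask <- function(rle) {
  vals <- rep(c(FALSE, TRUE), length.out = length(rle$runs))
  matrix(rep(vals, rle$runs), rle$dim[1], rle$dim[2])
}
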