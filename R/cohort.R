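#' Specification of a synthetic study cohort
#'
#' Describes the cohort the generator emulates: teeth with and without a
#' C-shaped canal, split over two native-resolution groups, with subject
#' covariates, a dentin-pulp volume covariate carrying a standardized group
#' difference, and paired zoomed / non-zoomed texture measurements with ROI
#' re-selection jitter under zoom.
#'
#' Defaults mirror the emulated study: 22 C-shaped vs 21 control teeth,
#' resolution split 10 + 16 (1023 x 496) and 12 + 5 (1023 x 593), volume
#' standardized difference 0.90 anchored at group means 383.86 / 452.48
#' mm^3, 67% male, 56% in the younger (17-39) age band.
#'
#' @param n_c_shaped,n_control group sizes (>= 0).
#' @param resolution_split list with elements `group_496` and `group_593`,
#'   each `c(c_shaped, control)` counts; must sum to the group sizes.
#'   `NULL` (the default) uses the matched 10+16 / 12+5 split for the
#'   default 22/21 sizes and otherwise allocates ~60% of each group to
#'   1023 x 496.
#' @param heterogeneity_effect standardized shift (in units of the
#'   between-tooth canal-contrast SD) added to the canal contrast of
#'   C-shaped teeth; 0 makes the texture metrics label-independent.
#' @param volume_effect_d standardized mean difference of the dentin-pulp
#'   volume covariate between groups.
#' @param sex_prob probability of `male`.
#' @param age_group_prob probability of the `17-39` age band.
#' @param zoom_factor_range interval of linear magnification factors drawn
#'   per tooth, within (1, 4].
#' @param roi_jitter_frac fractional perturbation of the re-selected ROI
#'   extent under zoom (each axis drawn within +/- `roi_jitter_frac / 2`).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_c_shaped = 22L, n_control = 21L,
                        resolution_split = NULL,
                        heterogeneity_effect = 1,
                        volume_effect_d = 0.90,
                        sex_prob = 29 / 43, age_group_prob = 24 / 43,
                        zoom_factor_range = c(1.15, 1.35),
                        roi_jitter_frac = 0.1, seed = 1L) {
  if (n_c_shaped < 0 || n_control < 0) stop("counts must be >= 0", call. = FALSE)
  if (sex_prob < 0 || sex_prob > 1 || age_group_prob < 0 || age_group_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (heterogeneity_effect < 0)
    stop("'heterogeneity_effect' must be >= 0", call. = FALSE)
  if (min(zoom_factor_range) <= 1 || max(zoom_factor_range) > 4)
    stop("'zoom_factor_range' must lie within (1, 4]", call. = FALSE)
  if (is.null(resolution_split)) {
    if (n_c_shaped == 22L && n_control == 21L) {
      # the emulated study's matched split
      resolution_split <- list(group_496 = c(10L, 16L), group_593 = c(12L, 5L))
    } else {
      # otherwise allocate ~60% (26/43) of each group to 1023 x 496
      split_of <- function(n) { g <- round(n * 26 / 43); c(g, n - g) }
      s1 <- split_of(n_c_shaped); s2 <- split_of(n_control)
      resolution_split <- list(group_496 = c(s1[1], s2[1]),
                               group_593 = c(s1[2], s2[2]))
    }
  }
  rs <- resolution_split
  if (!setequal(names(rs), c("group_496", "group_593")) ||
      any(vapply(rs, length, 0L) != 2L))
    stop("'resolution_split' must name group_496 and group_593, each c(c_shaped, control)",
         call. = FALSE)
  if (rs$group_496[1] + rs$group_593[1] != n_c_shaped ||
      rs$group_496[2] + rs$group_593[2] != n_control)
    stop("'resolution_split' totals disagree with the group counts",
         call. = FALSE)
  structure(list(n_c_shaped = as.integer(n_c_shaped),
                 n_control = as.integer(n_control),
                 resolution_split = lapply(rs, as.integer),
                 heterogeneity_effect = heterogeneity_effect,
                 volume_effect_d = volume_effect_d,
                 sex_prob = sex_prob, age_group_prob = age_group_prob,
                 zoom_factor_range = as.numeric(zoom_factor_range),
                 roi_jitter_frac = roi_jitter_frac,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d C-shaped + %d control (496: %d+%d, 593: %d+%d), delta = %g, volume d = %g, seed %d\n",
              x$n_c_shaped, x$n_control,
              x$resolution_split$group_496[1], x$resolution_split$group_496[2],
              x$resolution_split$group_593[1], x$resolution_split$group_593[2],
              x$heterogeneity_effect, x$volume_effect_d, x$seed))
  invisible(x)
}

# Between-tooth canal-contrast SD: the scale of heterogeneity_effect.
.contrast_sd <- 6
# Volume covariate: anchored near the emulated group means (383.86 /
# 452.48 mm^3); common SD chosen so the default d = 0.90 reproduces them.
.volume_base_mean <- 383.86
.volume_sd <- (452.48 - 383.86) / 0.90

#' Generate a synthetic cohort
#'
#' Draws one phantom per tooth, measures the three texture indices on the
#' native phantom, then digitally magnifies it by a per-tooth factor and
#' re-measures on a jitter-re-selected ROI, producing the paired zoomed /
#' non-zoomed bundles. C-shaped teeth get the C-shaped canal geometry and a
#' canal contrast shifted by `heterogeneity_effect` contrast-SDs; their
#' volume covariate is shifted by `volume_effect_d` volume-SDs. Sex, age
#' group and side carry no true effect on the metrics.
#'
#' @param spec a [cohort_spec].
#' @param power_p,power_scale,log_base index settings passed through to
#'   [texture_metrics()].
#' @param keep_images if `TRUE`, attach the phantom images as an attribute
#'   (for phantom dumps).
#' @return A data frame of class `xpar_cohort`, one row per tooth, with the
#'   label, covariates and the six metric values (plus the per-tooth zoom
#'   factor). The generating spec is attached as attribute `spec`.
#' @export
sample_cohort <- function(spec = cohort_spec(), power_p = 2, power_scale = 10,
                          log_base = exp(1), keep_images = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_c_shaped + spec$n_control
  labels <- c(rep(TRUE, spec$resolution_split$group_496[1]),
              rep(FALSE, spec$resolution_split$group_496[2]),
              rep(TRUE, spec$resolution_split$group_593[1]),
              rep(FALSE, spec$resolution_split$group_593[2]))
  resol <- c(rep("1023x496", sum(spec$resolution_split$group_496)),
             rep("1023x593", sum(spec$resolution_split$group_593)))
  if (n == 0L) return(empty_cohort(spec))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  rows <- vector("list", n)
  images <- if (keep_images) vector("list", n) else NULL
  for (i in seq_len(n)) {
    lab <- labels[i]
    sex <- if (stats::runif(1) < spec$sex_prob) "male" else "female"
    age <- if (stats::runif(1) < spec$age_group_prob) "17-39" else "40-54"
    side <- if (stats::runif(1) < 0.5) "right" else "left"
    volume <- stats::rnorm(1, .volume_base_mean +
                             lab * spec$volume_effect_d * .volume_sd, .volume_sd)
    volume <- max(volume, 50)
    plen <- max(stats::rnorm(1, 21.7, 1.4), 5)
    dentin_mean <- stats::runif(1, 165, 195)
    contrast <- stats::rnorm(1, 28 + lab * spec$heterogeneity_effect * .contrast_sd,
                             .contrast_sd)
    contrast <- min(max(contrast, 5), dentin_mean)
    pp <- phantom_params(
      roi_height = sample(42:58, 1), roi_width = sample(32:46, 1),
      dentin_mean = dentin_mean,
      dentin_gradient = stats::runif(1, 0.1, 0.3),
      canal_shape = if (lab) "c_shaped" else "simple",
      canal_contrast = contrast,
      canal_width = sample(5:7, 1),
      noise_sd = stats::runif(1, 1.5, 2.2), blur_sigma = 1)
    ph <- make_tooth_phantom(pp, rng_seed = sample.int(2147483646L, 1))
    roi <- ph$image
    nz <- texture_metrics(roi, "non_zoomed", power_p, power_scale, log_base)
    zf <- stats::runif(1, spec$zoom_factor_range[1], spec$zoom_factor_range[2])
    zimg <- digital_zoom(roi, zf, "bilinear")
    zroi <- jitter_reselect(zimg, pp$roi_height, pp$roi_width, zf,
                            spec$roi_jitter_frac)
    z <- texture_metrics(zroi, "zoomed", power_p, power_scale, log_base)
    rows[[i]] <- data.frame(
      tooth_id = sprintf("T%03d", i), c_shaped = lab, sex = sex,
      age_group = age, side = side, resolution_group = resol[i],
      dentin_pulp_volume = volume, pulp_length = plen,
      xpar_non_zoomed = nz$xpar, power_xpar_non_zoomed = nz$power_xpar,
      pixel_count_non_zoomed = nz$pixel_count,
      xpar_zoomed = z$xpar, power_xpar_zoomed = z$power_xpar,
      pixel_count_zoomed = z$pixel_count,
      zoom_factor = zf, stringsAsFactors = FALSE)
    if (keep_images) images[[i]] <- roi
  }
  out <- do.call(rbind, rows)
  class(out) <- c("xpar_cohort", "data.frame")
  attr(out, "spec") <- spec
  if (keep_images) attr(out, "images") <- images
  out
}

# Re-select an ROI on the zoomed image: the target extent is the native
# extent scaled by the zoom factor, perturbed per axis by the jitter
# fraction, at a random offset. Models the operator re-drawing the ROI on
# the magnified view, so zoomed pixel counts are not exact multiples of the
# native counts.
jitter_reselect <- function(zimg, h, w, factor, jitter_frac) {
  zh <- nrow(zimg$pixels); zw <- ncol(zimg$pixels)
  th <- round(h * factor * (1 + stats::runif(1, -jitter_frac / 2, jitter_frac / 2)))
  tw <- round(w * factor * (1 + stats::runif(1, -jitter_frac / 2, jitter_frac / 2)))
  th <- min(max(th, 8L), zh); tw <- min(max(tw, 8L), zw)
  r0 <- sample.int(zh - th + 1L, 1) - 1L
  c0 <- sample.int(zw - tw + 1L, 1) - 1L
  crop_roi(zimg, roi_rect(r0, c0, th, tw))
}

empty_cohort <- function(spec) {
  out <- data.frame(
    tooth_id = character(0), c_shaped = logical(0), sex = character(0),
    age_group = character(0), side = character(0),
    resolution_group = character(0), dentin_pulp_volume = numeric(0),
    pulp_length = numeric(0), xpar_non_zoomed = numeric(0),
    power_xpar_non_zoomed = numeric(0), pixel_count_non_zoomed = numeric(0),
    xpar_zoomed = numeric(0), power_xpar_zoomed = numeric(0),
    pixel_count_zoomed = numeric(0), zoom_factor = numeric(0),
    stringsAsFactors = FALSE)
  class(out) <- c("xpar_cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Write / read a cohort table as CSV
#'
#' One row per tooth: label, covariates and the six metric values. The CSV
#' written by [write_cohort_csv()] is accepted unchanged by
#' [read_cohort_csv()] and [run_study()].
#'
#' @param cohort an `xpar_cohort` data frame.
#' @param path CSV path.
#' @return `path` invisibly / the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("tooth_id", "c_shaped", "sex", "age_group", "resolution_group",
              "xpar_non_zoomed", "power_xpar_non_zoomed",
              "pixel_count_non_zoomed", "xpar_zoomed", "power_xpar_zoomed",
              "pixel_count_zoomed")
  missing <- setdiff(needed, names(out))
  if (length(missing))
    stop("cohort CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out$c_shaped <- as.logical(out$c_shaped)
  class(out) <- c("xpar_cohort", "data.frame")
  out
}

#' Read a cohort spec from a JSON config
#'
#' @param path JSON file with any subset of the [cohort_spec()] fields.
#' @return A [cohort_spec].
#' @export
read_cohort_spec_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  if (!is.null(cfg$resolution_split))
    cfg$resolution_split <- lapply(cfg$resolution_split, as.integer)
  do.call(cohort_spec, cfg)
}

#' Dump cohort phantoms as PNG files
#'
#' @param cohort a cohort generated with `keep_images = TRUE`.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
dump_phantoms <- function(cohort, dir) {
  imgs <- attr(cohort, "images")
  if (is.null(imgs))
    stop("cohort was not generated with keep_images = TRUE", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$tooth_id, ".png"))
  for (i in seq_along(imgs)) write_image_png(imgs[[i]], paths[i], rescale = FALSE)
  invisible(paths)
}
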