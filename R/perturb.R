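# Graded perturbation operators and synthetic scanner profiles used by the
# robustness harness. Severity triples are fixed, documented defaults; a
# "none" severity exists for every kind and is an exact identity.

PERTURBATION_KINDS <- c("intensity_scaling", "gaussian_noise",
                        "elastic_deformation", "motion_blur")
SEVERITY_LEVELS <- c("none", "low", "medium", "high")

# severity -> parameter maps (see the methods vignette for rationale)
.severity_params <- list(
  intensity_scaling = c(none = 1, low = 0.95, medium = 0.90, high = 0.80),   # gain
  gaussian_noise    = c(none = 0, low = 0.05, medium = 0.10, high = 0.20),   # sd / in-mask sd
  elastic_deformation = c(none = 0, low = 1, medium = 2, high = 4),          # max disp (vox)
  motion_blur       = c(none = 1, low = 2, medium = 3, high = 5)             # kernel length
)

#' Perturbation specification
#'
#' @param kind One of `intensity_scaling`, `gaussian_noise`,
#'   `elastic_deformation`, `motion_blur`.
#' @param severity One of `none`, `low`, `medium`, `high`.
#' @return Object of class `perturbation_spec` with the resolved parameter.
#' @export
perturbation_spec <- function(kind, severity = "low") {
  kind <- match.arg(kind, PERTURBATION_KINDS)
  severity <- match.arg(severity, SEVERITY_LEVELS)
  structure(list(kind = kind, severity = severity,
                 param = unname(.severity_params[[kind]][severity])),
            class = "perturbation_spec")
}

# smooth random displacement field with given max |d| per axis (voxels)
.elastic_field <- function(shape, max_disp, sigma = 3) {
  lapply(1:3, function(ax) {
    f <- smooth_noise_field(shape, sigma)
    m <- max(abs(f))
    if (m < .Machine$double.eps) array(0, dim = shape) else f / m * max_disp
  })
}

.warp_volume <- function(vol, disp) {
  gs <- dim(vol$channels[[1]])
  co <- voxel_grid_coords(gs)
  src <- cbind(co[, 1] + as.vector(disp[[1]]),
               co[, 2] + as.vector(disp[[2]]),
               co[, 3] + as.vector(disp[[3]]))
  vol$channels <- lapply(vol$channels, function(ch)
    array(trilinear_sample(ch, src), dim = gs))
  vol$brain_mask <- array(as.integer(nearest_sample(vol$brain_mask, src)), dim = gs)
  vol$region_mask <- array(as.integer(nearest_sample(vol$region_mask, src)), dim = gs)
  vol
}

#' Apply a graded perturbation to a volume
#'
#' Intensity-domain perturbations (`intensity_scaling`, `gaussian_noise`,
#' `motion_blur`) leave all labels and masks untouched; `elastic_deformation`
#' warps image, brain mask and region mask with the same displacement field.
#' The `none` severity is an exact identity for every kind.
#'
#' @param vol A `labeled_volume`.
#' @param pert A [perturbation_spec()], or a kind string.
#' @param seed Integer seed (noise, displacement field, blur direction).
#' @param severity Severity level when `pert` is given as a string.
#' @return Perturbed `labeled_volume` with unchanged class label.
#' @export
apply_perturbation <- function(vol, pert, seed = 0L, severity = "low") {
  stopifnot(inherits(vol, "labeled_volume"))
  if (is.character(pert)) pert <- perturbation_spec(pert, severity)
  stopifnot(inherits(pert, "perturbation_spec"))
  if (pert$severity == "none") return(vol)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(31L, seed, match(pert$kind, PERTURBATION_KINDS)))
  gs <- dim(vol$channels[[1]])
  switch(pert$kind,
    intensity_scaling = {
      vol$channels <- lapply(vol$channels, function(ch) ch * pert$param)
    },
    gaussian_noise = {
      msk <- vol$brain_mask > 0
      vol$channels <- lapply(vol$channels, function(ch) {
        s <- stats::sd(ch[msk]) * pert$param
        ch + s * array(stats::rnorm(prod(gs)), dim = gs)
      })
    },
    elastic_deformation = {
      disp <- .elastic_field(gs, pert$param)
      vol <- .warp_volume(vol, disp)
    },
    motion_blur = {
      ax <- sample.int(3L, 1L)
      L <- as.integer(pert$param)
      k <- rep(1 / L, L)
      vol$channels <- lapply(vol$channels, function(ch) .box_blur_axis(ch, k, ax))
    },
    stop("unknown perturbation kind: ", pert$kind)
  )
  vol
}

# renormalized 1-D box convolution along one axis (shared with .smooth_axis
# machinery but without Gaussian weights)
.box_blur_axis <- function(x, k, ax) .smooth_axis(x, k, ax)

SCANNER_PROFILES <- c("identity", "low_field", "bias_field", "coil_scaling",
                      "high_noise_low_contrast")

#' Scanner profile
#'
#' Parameterized rendering of acquisition characteristics:
#' `low_field` lowers SNR (extra noise plus mild resolution loss),
#' `bias_field` multiplies by an extra smooth intensity non-uniformity,
#' `coil_scaling` applies a smooth per-coil gain map, and
#' `high_noise_low_contrast` both raises the noise floor and shrinks
#' inter-tissue intensity gaps. `identity` leaves volumes untouched.
#'
#' @param profile_id One of `identity`, `low_field`, `bias_field`,
#'   `coil_scaling`, `high_noise_low_contrast`.
#' @param noise_factor Added noise sd as a fraction of in-mask sd.
#' @param bias_amplitude Log-amplitude of the profile's bias/gain field.
#' @param bias_smoothness_mm Field correlation length (mm).
#' @param contrast_factor Multiplier (< 1) on deviations from the in-mask
#'   mean for `high_noise_low_contrast`.
#' @param blur_sigma Gaussian blur sd in voxels for `low_field`.
#' @return Object of class `scanner_profile`.
#' @export
scanner_profile <- function(profile_id,
                            noise_factor = switch(profile_id,
                              low_field = 0.15, high_noise_low_contrast = 0.20, 0),
                            bias_amplitude = switch(profile_id,
                              bias_field = 0.4, coil_scaling = 0.3, 0),
                            bias_smoothness_mm = switch(profile_id,
                              coil_scaling = 10, 8),
                            contrast_factor = 0.6,
                            blur_sigma = 0.7) {
  profile_id <- match.arg(profile_id, SCANNER_PROFILES)
  structure(list(profile_id = profile_id, noise_factor = noise_factor,
                 bias_amplitude = bias_amplitude,
                 bias_smoothness_mm = bias_smoothness_mm,
                 contrast_factor = contrast_factor, blur_sigma = blur_sigma),
            class = "scanner_profile")
}

#' Apply a synthetic scanner profile
#'
#' Deterministic given `seed`; grid shape, masks and labels are preserved.
#'
#' @param vol A `labeled_volume`.
#' @param profile A [scanner_profile()] or profile id string.
#' @param seed Integer seed for field/noise draws.
#' @return Transformed `labeled_volume`.
#' @export
apply_scanner_profile <- function(vol, profile, seed = 0L) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (is.character(profile)) profile <- scanner_profile(profile)
  stopifnot(inherits(profile, "scanner_profile"))
  if (profile$profile_id == "identity") return(vol)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(47L, seed, match(profile$profile_id, SCANNER_PROFILES)))
  gs <- dim(vol$channels[[1]])
  msk <- vol$brain_mask > 0
  add_noise <- function(ch, factor) {
    if (factor <= 0) return(ch)
    ch + factor * stats::sd(ch[msk]) * array(stats::rnorm(prod(gs)), dim = gs)
  }
  switch(profile$profile_id,
    low_field = {
      vol$channels <- lapply(vol$channels, function(ch) {
        add_noise(gauss_smooth3(ch, profile$blur_sigma), profile$noise_factor)
      })
    },
    bias_field = ,
    coil_scaling = {
      sig <- profile$bias_smoothness_mm / mean(vol$spacing)
      vol$channels <- lapply(vol$channels, function(ch) {
        if (profile$bias_amplitude <= 0) return(ch)
        field <- exp(profile$bias_amplitude * smooth_noise_field(gs, sig))
        ch * field
      })
    },
    high_noise_low_contrast = {
      vol$channels <- lapply(vol$channels, function(ch) {
        m <- mean(ch[msk])
        ch2 <- ch
        ch2[msk] <- m + profile$contrast_factor * (ch[msk] - m)
        add_noise(ch2, profile$noise_factor)
      })
    },
    stop("unknown scanner profile: ", profile$profile_id)
  )
  vol
}
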