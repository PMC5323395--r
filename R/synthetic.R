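# Synthetic longitudinal cohorts with known ground truth. A smooth phantom
# "brain" (outer shell, interior tissue blobs, one designated structure at the
# effect region) stands in for the template; per-subject baseline anatomy is a
# random smooth diffeomorphism of the template; longitudinal change is a shared
# aging field plus, for converters, a localized contraction (volume loss) at
# the effect region, plus small smooth subject noise. Every stage of the
# pipeline can be validated against the returned ground-truth fields.

#' Cohort specification
#'
#' Defaults define the standard simulated study: 15 converters and 15 stable
#' subjects on a 48^3 grid, a contraction effect of 2 voxels peak displacement
#' in a radius-6 region, a shared aging field of 0.5 voxels, subject-level
#' longitudinal variability of 1 voxel (half the effect peak), inter-subject
#' anatomical variation of 2 voxels, and mild intensity noise.
#'
#' @param n_converters,n_stable group sizes.
#' @param shape scalar or length-3 grid size (voxels).
#' @param effect_center center of the converter effect region (voxels);
#'   default just off-center, inside the designated structure.
#' @param effect_radius Gaussian radius of the effect region (voxels).
#' @param effect_amplitude peak longitudinal contraction displacement for
#'   converters (voxels).
#' @param common_amplitude peak displacement of the shared aging field
#'   (voxels).
#' @param intersubject_amplitude peak displacement of per-subject baseline
#'   anatomy relative to the template (voxels).
#' @param longitudinal_noise_amplitude peak displacement of the smooth
#'   per-subject longitudinal noise field (voxels).
#' @param noise_sd standard deviation of additive intensity noise.
#' @param seed master seed; all per-subject randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_converters = 15L, n_stable = 15L, shape = 48L,
                        effect_center = NULL, effect_radius = NULL,
                        effect_amplitude = 2, common_amplitude = 0.5,
                        intersubject_amplitude = 2,
                        longitudinal_noise_amplitude = 1.0,
                        noise_sd = 0.02, seed = 1L) {
  if (length(shape) == 1) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (any(shape < 16L)) stop("cohort_spec: shape must be at least 16 voxels per axis")
  if (is.null(effect_center)) effect_center <- round(shape * c(0.40, 0.56, 0.50))
  if (is.null(effect_radius)) effect_radius <- max(3, round(min(shape) / 8))
  amps <- c(effect_amplitude, common_amplitude, intersubject_amplitude,
            longitudinal_noise_amplitude)
  if (any(amps < 0) || noise_sd < 0) stop("cohort_spec: amplitudes must be >= 0")
  if (any(effect_center < 1) || any(effect_center > shape))
    stop("cohort_spec: effect region outside grid")
  structure(list(n_converters = as.integer(n_converters),
                 n_stable = as.integer(n_stable), shape = shape,
                 effect_center = as.numeric(effect_center),
                 effect_radius = as.numeric(effect_radius),
                 effect_amplitude = effect_amplitude,
                 common_amplitude = common_amplitude,
                 intersubject_amplitude = intersubject_amplitude,
                 longitudinal_noise_amplitude = longitudinal_noise_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Smooth phantom template and brain mask
#'
#' Builds a smooth spherical "brain" with a bright outer shell, a dark
#' central ventricle-like cavity, several tissue blobs of distinct intensity
#' (providing gradient information throughout the volume), a designated bright
#' structure centered at `effect_center`, and a low-frequency seeded texture.
#' Intensities lie in `[0, 1]`; the binary mask covers the brain interior and
#' is a single connected component by construction.
#'
#' @param shape scalar or length-3 grid size.
#' @param seed integer seed (the phantom is deterministic given the seed).
#' @param effect_center,effect_radius location and radius of the designated
#'   structure; defaults as in [cohort_spec()].
#' @return List with `template` and binary `mask`, both [scalar_volume()]s.
#' @export
make_template <- function(shape = 48L, seed = 1L, effect_center = NULL,
                          effect_radius = NULL) {
  if (length(shape) == 1) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (is.null(effect_center)) effect_center <- round(shape * c(0.40, 0.56, 0.50))
  if (is.null(effect_radius)) effect_radius <- max(3, round(min(shape) / 8))

  ctr <- (shape + 1) / 2
  pos <- grid_positions(shape)
  gx <- array(pos$x, shape); gy <- array(pos$y, shape); gz <- array(pos$z, shape)
  rx <- 0.42 * shape[1]; ry <- 0.40 * shape[2]; rz <- 0.41 * shape[3]
  r <- sqrt(((gx - ctr[1]) / rx)^2 + ((gy - ctr[2]) / ry)^2 +
            ((gz - ctr[3]) / rz)^2)
  mask <- r <= 1

  img <- array(0, shape)
  img[mask] <- 0.5                                   # tissue base
  img[r > 1 & r <= 1.12] <- 0.9                      # skull-like shell

  bump <- function(center, radius, amp) {
    d2 <- (gx - center[1])^2 + (gy - center[2])^2 + (gz - center[3])^2
    amp * exp(-d2 / (2 * radius^2))
  }
  # central dark cavity
  img <- img - bump(ctr, 0.12 * min(shape), 0.4) * mask
  # fixed tissue blobs spread through the volume (deterministic layout)
  offs <- rbind(c( 0.18,  0.10, -0.12), c(-0.16,  0.16,  0.10),
                c( 0.05, -0.20,  0.15), c(-0.12, -0.14, -0.15),
                c( 0.20, -0.05,  0.05), c(-0.05,  0.05,  0.20))
  amp <- c(0.30, -0.25, 0.28, -0.22, 0.24, -0.20)
  for (k in seq_len(nrow(offs))) {
    img <- img + bump(ctr + offs[k, ] * shape, 0.09 * min(shape), amp[k]) * mask
  }
  # designated structure at the effect region
  img <- img + bump(effect_center, effect_radius, 0.35) * mask

  # seeded low-frequency texture for dense gradient information
  with_seed(seed, {
    tex <- array(rnorm(prod(shape)), shape)
  })
  tex <- smooth3(tex, 2.5)
  tex <- tex / max(abs(tex))
  img <- img + 0.08 * tex * mask

  img <- smooth3(img, 1)
  img <- pmin(pmax(img, 0), 1)
  list(template = scalar_volume(array(img, shape)),
       mask = scalar_volume(array(as.numeric(mask), shape)))
}

#' Random smooth stationary velocity field
#'
#' Gaussian-smoothed white noise, scaled so the maximum vector magnitude
#' equals `max_norm`, optionally tapered to zero outside a (smoothed) mask so
#' that the field acts only where there is anatomy.
#'
#' @param shape scalar or length-3 grid size.
#' @param sigma smoothing standard deviation (voxels) controlling spatial
#'   scale.
#' @param max_norm maximum displacement magnitude (voxels).
#' @param seed integer seed.
#' @param support optional binary mask; the field is multiplied by a smooth
#'   taper of it.
#' @return A [velocity_field()].
#' @export
random_smooth_svf <- function(shape, sigma = 4, max_norm = 1, seed = 1L,
                              support = NULL) {
  if (length(shape) == 1) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  with_seed(seed, {
    v <- array(rnorm(prod(shape) * 3), c(shape, 3L))
  })
  for (c in 1:3) v[, , , c] <- smooth3(v[, , , c], sigma)
  if (!is.null(support)) {
    taper <- smooth3(unclass(as_volume(support)) * 1.0, 2)
    for (c in 1:3) v[, , , c] <- v[, , , c] * taper
  }
  mx <- max(sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2))
  if (mx > 0 && max_norm > 0) v <- v * (max_norm / mx) else v[] <- 0
  velocity_field(v)
}

# Localized radial contraction centered at `center`: displacement
# -A * (x - c)/r0 * exp(-|x - c|^2 / (2 r0^2)) rescaled to peak amplitude A.
contraction_field <- function(shape, center, radius, amplitude) {
  pos <- grid_positions(shape)
  dx <- pos$x - center[1]; dy <- pos$y - center[2]; dz <- pos$z - center[3]
  d2 <- dx^2 + dy^2 + dz^2
  g <- exp(-d2 / (2 * radius^2)) / radius
  # peak of t*exp(-t^2/2) is exp(-1/2); rescale so max |v| = amplitude
  scale <- -amplitude / exp(-0.5)
  v <- array(0, c(shape, 3L))
  v[, , , 1] <- array(scale * g * dx, shape)
  v[, , , 2] <- array(scale * g * dy, shape)
  v[, , , 3] <- array(scale * g * dz, shape)
  velocity_field(v)
}

#' Generate one synthetic subject
#'
#' Baseline anatomy is `I0 = template o Exp(v_anat)` plus intensity noise,
#' with `v_anat` a random smooth SVF of amplitude
#' `intersubject_amplitude`. Longitudinal change is
#' `v_long = common aging field + (converters only) localized contraction +
#' small smooth noise`, and `I1 = I0 o Exp(v_long)` plus intensity noise.
#' The same subject seed produces identical shared and noise components for
#' either label, so a converter and a stable subject with the same seed
#' differ only inside the effect region.
#'
#' @param template,mask output of [make_template()].
#' @param spec a [cohort_spec()].
#' @param group `"MCIc"` (converter) or `"MCIs"` (stable).
#' @param subject_seed integer seed for this subject.
#' @return List with `I0`, `I1` ([scalar_volume()]s), `v_long_true`,
#'   `v_anat_true` ([velocity_field()]s) and `label`.
#' @export
make_subject <- function(template, mask, spec, group = c("MCIc", "MCIs"),
                         subject_seed = 1L) {
  group <- match.arg(group)
  shape <- grid_shape(template)
  sup <- interior_support(mask)
  v_anat <- random_smooth_svf(shape, sigma = 6,
                              max_norm = spec$intersubject_amplitude,
                              seed = subject_seed, support = sup)
  I0 <- warp_image(template, exp_svf(v_anat, 1))

  v_common <- random_smooth_svf(shape, sigma = 6,
                                max_norm = spec$common_amplitude,
                                seed = spec$seed %% 1000000000L + 7919L, support = sup)
  v_noise <- random_smooth_svf(shape, sigma = 4,
                               max_norm = spec$longitudinal_noise_amplitude,
                               seed = subject_seed %% 1000000000L + 104729L,
                               support = sup)
  v_long <- unclass(v_common) + unclass(v_noise)
  if (group == "MCIc" && spec$effect_amplitude > 0) {
    v_long <- v_long + unclass(contraction_field(shape, spec$effect_center,
                                                 spec$effect_radius,
                                                 spec$effect_amplitude))
  }
  v_long <- velocity_field(v_long)

  jd_min <- min(unclass(jacobian_determinant(exp_svf(v_long, 1))),
                unclass(jacobian_determinant(exp_svf(v_anat, 1))))
  if (jd_min <= 0)
    stop("make_subject: ground-truth deformation is not diffeomorphic; ",
         "reduce the spec amplitudes")

  with_seed(subject_seed %% 1000000000L + 15485863L, {
    n0 <- array(rnorm(prod(shape), sd = spec$noise_sd), shape)
    n1 <- array(rnorm(prod(shape), sd = spec$noise_sd), shape)
  })
  I0 <- scalar_volume(pmin(pmax(unclass(I0) + n0, 0), 1))
  I1 <- warp_image(I0, exp_svf(v_long, 1))
  I1 <- scalar_volume(pmin(pmax(unclass(I1) + n1, 0), 1))
  list(I0 = I0, I1 = I1, v_long_true = v_long, v_anat_true = v_anat,
       label = group)
}

#' Generate a full synthetic cohort
#'
#' Builds the phantom template and all subjects of a [cohort_spec()]. With
#' `dir = NULL` everything is returned in memory; otherwise template, mask,
#' per-subject baseline/follow-up images and ground-truth SVFs are written as
#' NIfTI under `dir` together with a `manifest.csv` (columns `subject_id`,
#' `baseline_path`, `followup_path`, `label`, plus the recorded seed). The
#' cohort is fully reproducible from the spec.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param overwrite allow writing into an existing directory.
#' @return Invisibly (when writing) or visibly (in memory) a list with
#'   `template`, `mask`, `subjects`, `manifest` and `spec`.
#' @export
make_cohort <- function(spec = cohort_spec(), dir = NULL, overwrite = FALSE) {
  tpl <- make_template(spec$shape, seed = spec$seed,
                       effect_center = spec$effect_center,
                       effect_radius = spec$effect_radius)
  n <- spec$n_converters + spec$n_stable
  labels <- c(rep("MCIc", spec$n_converters), rep("MCIs", spec$n_stable))
  with_seed(spec$seed, {
    sub_seeds <- sample.int(2000000000L, n)
  })
  subjects <- vector("list", n)
  ids <- sprintf("sub%03d", seq_len(n))
  for (i in seq_len(n)) {
    subjects[[i]] <- make_subject(tpl$template, tpl$mask, spec,
                                  group = labels[i],
                                  subject_seed = sub_seeds[i])
  }
  manifest <- data.frame(subject_id = ids,
                         baseline_path = file.path("subjects", paste0(ids, "_I0.nii.gz")),
                         followup_path = file.path("subjects", paste0(ids, "_I1.nii.gz")),
                         label = labels, seed = spec$seed,
                         stringsAsFactors = FALSE)
  out <- list(template = tpl$template, mask = tpl$mask, subjects = subjects,
              manifest = manifest, spec = spec)
  if (is.null(dir)) return(out)

  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("make_cohort: output directory exists; use overwrite = TRUE")
  dir.create(file.path(dir, "subjects"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_volume(tpl$template, file.path(dir, "template.nii.gz"))
  write_volume(tpl$mask, file.path(dir, "mask.nii.gz"))
  for (i in seq_len(n)) {
    write_volume(subjects[[i]]$I0, file.path(dir, manifest$baseline_path[i]))
    write_volume(subjects[[i]]$I1, file.path(dir, manifest$followup_path[i]))
    write_field(subjects[[i]]$v_long_true,
                file.path(dir, "truth", paste0(ids[i], "_vlong.nii.gz")))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}

#' Known-warp registration fixture
#'
#' A standard validation pair: the phantom template is warped by a known
#' diffeomorphic SVF composed of (a) a random smooth interior field supported
#' well inside the brain (where the phantom carries texture in every
#' direction) and (b) a radial contraction of the outer rim. The split
#' reflects what intensity-driven registration can observe: tangential motion
#' of the near-spherical rim is invisible to any similarity force (the
#' aperture problem), so the fixture keeps rim motion radial and confines the
#' free-form component to the textured interior. The combined field is scaled
#' to `max_norm` peak displacement.
#'
#' @param shape scalar or length-3 grid size (default 32).
#' @param template_seed,field_seed seeds of the phantom and of the interior
#'   field.
#' @param max_norm peak displacement of the combined true field (voxels,
#'   default 3).
#' @return List with `fixed` (warped image), `moving` (the template),
#'   `v_true` ([velocity_field()]), `phi_true` (its exponential), `mask` and
#'   `template`.
#' @export
registration_fixture <- function(shape = 32L, template_seed = 3L,
                                 field_seed = 21L, max_norm = 3) {
  if (length(shape) == 1) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  tpl <- make_template(shape, seed = template_seed)
  sup <- interior_support(tpl$mask)
  v_int <- random_smooth_svf(shape, sigma = 9, max_norm = 2.0,
                             seed = field_seed, support = sup)
  ctr <- (shape + 1) / 2
  g <- grid_positions(shape)
  dx <- g$x - ctr[1]; dy <- g$y - ctr[2]; dz <- g$z - ctr[3]
  r <- sqrt(dx^2 + dy^2 + dz^2); r[r == 0] <- 1
  prof <- -2.2 * exp(-(r - 0.42 * min(shape))^2 / (2 * (0.13 * min(shape))^2))
  vb <- array(0, c(shape, 3L))
  vb[, , , 1] <- array(prof * dx / r, shape)
  vb[, , , 2] <- array(prof * dy / r, shape)
  vb[, , , 3] <- array(prof * dz / r, shape)
  v <- unclass(v_int) + vb
  mx <- max(sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2))
  if (mx > 0) v <- v * (max_norm / mx)
  v_true <- velocity_field(v)
  phi_true <- exp_svf(v_true, 1)
  list(fixed = warp_image(tpl$template, phi_true), moving = tpl$template,
       v_true = v_true, phi_true = phi_true, mask = tpl$mask,
       template = tpl$template)
}

#' Parallel-transport fixture
#'
#' A template/subject pair with known ground truth for validating Schild's
#' Ladder: the subject baseline `I0` is the phantom template warped by a
#' random smooth inter-subject field, and the follow-up `I1` is `I0` warped
#' by a known within-subject longitudinal field. Both fields are supported in
#' the textured brain interior (see [registration_fixture()] for why rim
#' motion is restricted).
#'
#' @param shape scalar or length-3 grid size (default 32).
#' @param template_seed,anat_seed,long_seed seeds of the phantom, the
#'   inter-subject field and the longitudinal field.
#' @param anat_amplitude,long_amplitude peak displacements (voxels).
#' @return List with `T0` (template), `I0`, `I1`, `v_anat_true`,
#'   `v_long_true` and `mask`.
#' @export
transport_fixture <- function(shape = 32L, template_seed = 3L,
                              anat_seed = 101L, long_seed = 202L,
                              anat_amplitude = 1.5, long_amplitude = 1.5) {
  if (length(shape) == 1) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  tpl <- make_template(shape, seed = template_seed)
  sup <- interior_support(tpl$mask)
  v_anat <- random_smooth_svf(shape, sigma = 8, max_norm = anat_amplitude,
                              seed = anat_seed, support = sup)
  I0 <- warp_image(tpl$template, exp_svf(v_anat, 1))
  v_long <- random_smooth_svf(shape, sigma = 8, max_norm = long_amplitude,
                              seed = long_seed, support = sup)
  I1 <- warp_image(I0, exp_svf(v_long, 1))
  list(T0 = tpl$template, I0 = I0, I1 = I1, v_anat_true = v_anat,
       v_long_true = v_long, mask = tpl$mask)
}

# binary support comfortably inside the brain mask (where the phantom is
# textured in every direction); erosion scales with grid size
interior_support <- function(mask) {
  mk <- unclass(mask)
  sig <- max(2, round(min(dim(mk)) / 8))
  sup <- smooth3(mk, sig) > 0.92
  if (!any(sup)) stop("interior_support: mask too small for interior erosion")
  scalar_volume(array(as.numeric(sup), dim(mk)))
}

#' Ground-truth effect region of a cohort spec
#'
#' The localization target for group-difference maps: the voxels where the
#' converter-only component of the true longitudinal field (the seeded
#' contraction) has displacement magnitude of at least `threshold` voxels.
#' The contraction's Gaussian profile extends well beyond its nominal radius,
#' so a fixed-radius ball would understate where the groups truly differ.
#'
#' @param spec a [cohort_spec()].
#' @param threshold minimum true group-difference displacement (voxels,
#'   default 0.2) for a voxel to count as part of the effect.
#' @param mask optional binary brain mask to intersect with.
#' @return A binary [scalar_volume()].
#' @export
effect_region_mask <- function(spec, threshold = 0.2, mask = NULL) {
  vd <- contraction_field(spec$shape, spec$effect_center, spec$effect_radius,
                          spec$effect_amplitude)
  mag <- vector_norm3(vd)
  out <- array(as.numeric(mag >= threshold), spec$shape)
  if (!is.null(mask)) out <- out * unclass(as_volume(mask))
  scalar_volume(out)
}

# Evaluate `expr` under a temporary RNG seed, restoring caller RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
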