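#' Specify a 4D BOLD phantom
#'
#' Configuration for synthetic resting-state runs that carry the statistical
#' structure the downstream analysis assumes: a labelled blob atlas with two
#' gray-matter "hub" regions (an L-STG-like lateral temporal blob and an
#' L-PCu-like medial posterior blob) whose voxels load on shared band-limited
#' latent signals with group- and timepoint-dependent strength, non-hub
#' gray-matter blobs with fixed background connectivity, white-matter and CSF
#' compartments with their own latents, white noise, a per-voxel linear
#' drift, and a random-walk motion trace.
#'
#' `hub_strength` is a 3 x 2 matrix (rows CN / Obj-SCD / MCI, columns
#' baseline / month6) giving the latent loading of hub voxels. The default
#' plants the published qualitative pattern: Obj-SCD highest at baseline and
#' declining fastest by month 6.
#'
#' @param grid 3D voxel dimensions (default `c(24, 24, 16)`).
#' @param voxel_size_mm Isotropic voxel size (default 3.31).
#' @param n_volumes Number of volumes (default 140).
#' @param tr_s Repetition time in seconds (default 3).
#' @param hub_strength 3 x 2 matrix of hub loadings (see Details).
#' @param background_loading Loading of non-hub gray-matter blobs on their
#'   blob latents (default 0.3, placing background within-blob correlations after band-pass
#'   below the degree threshold so hubs dominate both centrality metrics).
#' @param noise_sd White-noise SD (default 1).
#' @param drift_sd SD of the per-voxel linear drift amplitude over the run
#'   (default 0.5).
#' @param subject_sd SD of the participant-level random effect added to the
#'   hub loading, shared across timepoints (default 0.1).
#' @param motion_scale Random-walk step SD for the translation parameters in
#'   mm (rotations use `motion_scale / 50`; default 0.05).
#' @param excess_motion_fraction Fraction of participants whose trace
#'   receives a >3 mm step, exercising motion exclusion (default 0).
#' @param hub_profile_range Range of the radial loading profile inside hub
#'   blobs (default `c(0.4, 1)`), making connectedness graded so that degree
#'   counts respond to `hub_strength`.
#' @param seed Integer seed; every run's stream is derived from it and the
#'   participant/timepoint identity.
#' @return An object of class `phantom_spec` (includes the built `atlas`).
#' @seealso [generate_bold_run()], [generate_longitudinal_pair()]
#' @export
phantom_spec <- function(grid = c(24, 24, 16),
                         voxel_size_mm = 3.31,
                         n_volumes = 140,
                         tr_s = 3,
                         hub_strength = default_hub_strength(),
                         background_loading = 0.3,
                         noise_sd = 1,
                         drift_sd = 0.5,
                         subject_sd = 0.1,
                         motion_scale = 0.05,
                         excess_motion_fraction = 0,
                         hub_profile_range = c(0.4, 1),
                         seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3 || any(grid < 10)) stopf("`grid` must be 3 dimensions, each >= 10")
  hub_strength <- as.matrix(hub_strength)
  if (!all(dim(hub_strength) == c(3, 2))) stopf("`hub_strength` must be 3 groups x 2 timepoints")
  if (any(hub_strength < 0)) stopf("`hub_strength` must be >= 0")
  if (n_volumes <= 28 + 10) stopf("`n_volumes` must exceed the nuisance count plus discard")
  dimnames(hub_strength) <- list(c("CN", "Obj-SCD", "MCI"), c("baseline", "month6"))
  atlas <- build_phantom_atlas(grid)
  structure(
    list(grid = grid, voxel_size_mm = voxel_size_mm, n_volumes = as.integer(n_volumes),
         tr_s = tr_s, hub_strength = hub_strength,
         background_loading = background_loading, noise_sd = noise_sd,
         drift_sd = drift_sd, subject_sd = subject_sd, motion_scale = motion_scale,
         excess_motion_fraction = excess_motion_fraction,
         hub_profile_range = hub_profile_range, atlas = atlas,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$grid, collapse = " x "), " @ ",
      x$voxel_size_mm, " mm, ", x$n_volumes, " volumes, TR ", x$tr_s, " s\n", sep = "")
  cat("  hub strength (baseline/month6): ",
      paste(rownames(x$hub_strength),
            apply(round(x$hub_strength, 2), 1, paste, collapse = "/"),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# default per-group hub loadings: Obj-SCD highest at baseline, declining
# fastest over the follow-up interval
default_hub_strength <- function() {
  matrix(c(0.9, 2.0, 1.05,
           0.85, 1.0, 0.95),
         nrow = 3, dimnames = list(c("CN", "Obj-SCD", "MCI"), c("baseline", "month6")))
}

# place an ellipsoid blob mask on the grid
ellipsoid_mask <- function(grid, center, radii) {
  ix <- array(rep(seq_len(grid[1]), times = grid[2] * grid[3]), grid)
  iy <- array(rep(rep(seq_len(grid[2]), each = grid[1]), times = grid[3]), grid)
  iz <- array(rep(seq_len(grid[3]), each = grid[1] * grid[2]), grid)
  ((ix - center[1]) / radii[1])^2 + ((iy - center[2]) / radii[2])^2 +
    ((iz - center[3]) / radii[3])^2 <= 1
}

#' Build the phantom blob atlas
#'
#' Labels the phantom grid with two gray-matter hub blobs (`stg`, `pcu`),
#' three non-hub gray-matter blobs, a white-matter core and a CSF
#' compartment, and derives tissue probability maps (0.95 inside the
#' compartment, 0.02 outside).
#'
#' @param grid 3D integer dimensions.
#' @return List with `labels` (character 3D array, `""` = background),
#'   `regions` (named list of logical masks), `gm_prob`, `wm_prob`,
#'   `csf_prob`, and `hub` (logical mask of the two hub blobs).
#' @export
build_phantom_atlas <- function(grid) {
  g <- grid
  scale <- g / c(24, 24, 16)
  pos <- function(p) pmax(1, round(p * scale))
  rad <- function(r) pmax(1.5, r * min(scale))
  # hubs are kept a small fraction (~10-15%) of total gray matter so that
  # per-subject map standardization does not absorb the planted hub contrast
  regions <- list(
    stg = ellipsoid_mask(g, pos(c(5, 13, 7)),  rep(rad(2.0), 3)),
    pcu = ellipsoid_mask(g, pos(c(10, 4, 11)), rep(rad(2.0), 3)),
    gm1 = ellipsoid_mask(g, pos(c(17, 16, 5)), rep(rad(3.4), 3)),
    gm2 = ellipsoid_mask(g, pos(c(7, 19, 11)), rep(rad(3.4), 3)),
    gm3 = ellipsoid_mask(g, pos(c(18, 7, 11)), rep(rad(3.4), 3)),
    gm4 = ellipsoid_mask(g, pos(c(5, 6, 4)),   rep(rad(3.4), 3)),
    gm5 = ellipsoid_mask(g, pos(c(19, 19, 12)), rep(rad(3.0), 3)),
    wm  = ellipsoid_mask(g, pos(c(12, 12, 8)), rad(3.2) * c(1.4, 1.4, 1)),
    csf = ellipsoid_mask(g, pos(c(12, 18, 6)), rep(rad(2.2), 3))
  )
  # gray matter wins where blobs would overlap white matter / CSF
  gm_names <- grep("^(stg|pcu|gm)", names(regions), value = TRUE)
  gm <- Reduce(`|`, regions[gm_names])
  regions$wm <- regions$wm & !gm
  regions$csf <- regions$csf & !gm & !regions$wm
  if (!any(regions$stg) || !any(regions$pcu)) stopf("grid too small to contain the hub blobs")
  labels <- array("", g)
  for (nm in names(regions)) labels[regions[[nm]] & labels == ""] <- nm
  prob <- function(mask) array(ifelse(mask, 0.95, 0.02), g)
  list(labels = labels, regions = regions,
       gm_prob = prob(gm), wm_prob = prob(regions$wm), csf_prob = prob(regions$csf),
       hub = regions$stg | regions$pcu)
}

# band-limited unit-variance latent signal: ideal-band-passed white noise
band_limited_latent <- function(n_volumes, tr, low = 0.01, high = 0.1) {
  x <- bandpass_filter(rnorm(n_volumes), low = low, high = high, tr = tr)
  s <- sd(x)
  if (s == 0) x else x / s
}

#' Generate one synthetic BOLD run
#'
#' Simulates a 4D resting-state run for one participant and timepoint under a
#' [phantom_spec()]: hub voxels load on a shared band-limited latent with
#' strength `hub_strength[group, timepoint]` (plus a participant random
#' effect shared across timepoints) scaled by a radial profile; non-hub
#' gray-matter blobs, white matter and CSF each share their own latent; all
#' voxels receive white noise and a linear drift. A random-walk motion trace
#' is emitted, with an injected >3 mm step for the configured fraction of
#' participants.
#'
#' @param spec A [phantom_spec()].
#' @param participant Participant identifier (string or integer); determines
#'   the participant-level random stream.
#' @param group `"CN"`, `"Obj-SCD"` or `"MCI"`.
#' @param timepoint `"baseline"` or `"month6"`.
#' @return A `bold_run`: list with 4D `data`, `tr`, `motion` (T x 6),
#'   tissue probability maps, `atlas`, identifiers and provenance.
#' @export
#' @examples
#' sp <- phantom_spec(grid = c(14, 14, 10), n_volumes = 60, seed = 1)
#' run <- generate_bold_run(sp, "S01", "Obj-SCD", "baseline")
#' dim(run$data)
generate_bold_run <- function(spec, participant, group, timepoint = "baseline") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!group %in% rownames(spec$hub_strength)) stopf("unknown group `%s`", group)
  if (!timepoint %in% colnames(spec$hub_strength)) stopf("unknown timepoint `%s`", timepoint)

  # participant-level quantities shared across timepoints
  subj <- with_seed(child_seed(spec$seed, "participant", participant), {
    list(
      strength_re = rnorm(1, 0, spec$subject_sd),
      excess_motion = runif(1) < spec$excess_motion_fraction
    )
  })

  with_seed(child_seed(spec$seed, "run", participant, timepoint), {
    g <- spec$grid
    nt <- spec$n_volumes
    at <- spec$atlas
    nvox <- prod(g)
    data <- matrix(rnorm(nvox * nt, 0, spec$noise_sd), nvox, nt)

    # linear drift, per voxel
    trend <- seq_len(nt) - (nt + 1) / 2
    trend <- trend / max(abs(trend))
    data <- data + outer(rnorm(nvox, 0, spec$drift_sd), trend)

    strength <- max(0, spec$hub_strength[group, timepoint] + subj$strength_re)
    pr <- spec$hub_profile_range
    # the two hub blobs share a common latent component (coupling 0.7), as
    # network hubs do; this keeps the leading eigenvector of the voxel-wise
    # correlation spanning both hubs instead of flipping between them
    coupling <- 0.85
    shared <- band_limited_latent(nt, spec$tr_s)
    for (hub in c("stg", "pcu")) {
      mask <- at$regions[[hub]]
      idx <- which(mask)
      # radial loading profile: 1 at blob centroid, decaying to the range min
      ctr <- colMeans(which(mask, arr.ind = TRUE))
      co <- which(mask, arr.ind = TRUE)
      dist <- sqrt(rowSums(sweep(co, 2, ctr)^2))
      prof <- pr[2] - (pr[2] - pr[1]) * dist / max(dist, 1)
      latent <- coupling * shared +
        sqrt(1 - coupling^2) * band_limited_latent(nt, spec$tr_s)
      data[idx, ] <- data[idx, ] + (strength * prof) %o% latent
    }
    for (blob in grep("^gm", names(at$regions), value = TRUE)) {
      idx <- which(at$regions[[blob]])
      latent <- band_limited_latent(nt, spec$tr_s)
      data[idx, ] <- data[idx, ] + spec$background_loading * rep(1, length(idx)) %o% latent
    }
    for (tis in c("wm", "csf")) {
      idx <- which(at$regions[[tis]])
      latent <- band_limited_latent(nt, spec$tr_s)
      data[idx, ] <- data[idx, ] + 0.9 * rep(1, length(idx)) %o% latent
    }

    motion <- cbind(
      apply(matrix(rnorm(nt * 3, 0, spec$motion_scale), nt, 3), 2, cumsum),
      apply(matrix(rnorm(nt * 3, 0, spec$motion_scale / 50), nt, 3), 2, cumsum)
    )
    if (subj$excess_motion) {
      at_frame <- sample(seq(nt %/% 2, nt), 1)
      motion[at_frame:nt, 1] <- motion[at_frame:nt, 1] + 5
    }
    colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

    structure(
      list(data = array(data, c(g, nt)), tr = spec$tr_s,
           voxel_size_mm = spec$voxel_size_mm, motion = motion,
           gm_prob = at$gm_prob, wm_prob = at$wm_prob, csf_prob = at$csf_prob,
           atlas = at, participant_id = as.character(participant), group = group,
           timepoint = timepoint, hub_strength_used = strength,
           steps = "generate_bold_run"),
      class = "bold_run"
    )
  })
}

#' Generate a longitudinal pair of runs
#'
#' Baseline and month-6 runs for one participant, sharing the
#' participant-level random effect on hub loading so within-subject change
#' reflects the per-group decline encoded in the spec's `hub_strength`
#' columns.
#'
#' @inheritParams generate_bold_run
#' @return List with elements `baseline` and `month6`, each a `bold_run`.
#' @export
generate_longitudinal_pair <- function(spec, participant, group) {
  list(
    baseline = generate_bold_run(spec, participant, group, "baseline"),
    month6 = generate_bold_run(spec, participant, group, "month6")
  )
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run> ", paste(dim(x$data), collapse = " x "), ", TR ", x$tr, " s",
      if (!is.null(x$participant_id)) paste0(" [", x$participant_id, " ", x$group %||% "",
                                             " ", x$timepoint %||% "", "]"),
      "\n", sep = "")
  invisible(x)
}

#' Write / read a BOLD run on disk
#'
#' Serializes the 4D series and tissue maps as NIfTI-1 and the motion trace
#' as 6-column whitespace-delimited text (3 translations in mm, 3 rotations
#' in rad), the on-disk exchange format of the pipeline.
#'
#' @param run A `bold_run`.
#' @param prefix Path prefix; files `<prefix>_bold.nii.gz`,
#'   `<prefix>_{gm,wm,csf}.nii.gz` and `<prefix>_motion.txt` are written.
#' @return `write_bold_run()` returns the prefix invisibly;
#'   `read_bold_run()` returns a `bold_run`.
#' @export
write_bold_run <- function(run, prefix) {
  vs <- run$voxel_size_mm %||% 3.31
  RNifti::writeNifti(RNifti::asNifti(run$data, pixdim = c(rep(vs, 3), run$tr)),
                     paste0(prefix, "_bold.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(run$gm_prob, pixdim = rep(vs, 3)),
                     paste0(prefix, "_gm.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(run$wm_prob, pixdim = rep(vs, 3)),
                     paste0(prefix, "_wm.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(run$csf_prob, pixdim = rep(vs, 3)),
                     paste0(prefix, "_csf.nii.gz"))
  utils::write.table(run$motion, paste0(prefix, "_motion.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_bold_run
#' @param tr Repetition time for runs read from disk (default 3).
#' @export
read_bold_run <- function(prefix, tr = 3) {
  img <- RNifti::readNifti(paste0(prefix, "_bold.nii.gz"))
  motion <- as.matrix(utils::read.table(paste0(prefix, "_motion.txt")))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  structure(
    list(data = array(as.numeric(img), dim = dim(img)), tr = tr,
         voxel_size_mm = RNifti::pixdim(img)[1],
         motion = motion,
         gm_prob = array(as.numeric(RNifti::readNifti(paste0(prefix, "_gm.nii.gz"))),
                         dim = dim(img)[1:3]),
         wm_prob = array(as.numeric(RNifti::readNifti(paste0(prefix, "_wm.nii.gz"))),
                         dim = dim(img)[1:3]),
         csf_prob = array(as.numeric(RNifti::readNifti(paste0(prefix, "_csf.nii.gz"))),
                          dim = dim(img)[1:3]),
         steps = "read_bold_run"),
    class = "bold_run"
  )
}
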