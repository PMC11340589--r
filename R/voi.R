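#' Voxel volumes and VOI masks
#'
#' `image_volume()` wraps a 3D voxel array with its spacing and flavor: CT
#' volumes hold Hounsfield units, PET volumes hold activity concentration in
#' kBq/mL. `voi_mask()` wraps a logical array aligned to such a volume.
#' The canonical reconstruction grid is 2.344 mm isotropic.
#'
#' @param values 3D numeric array (HU for `ct`, kBq/mL for `pet`).
#' @param spacing Voxel spacing in mm, length 3 (or scalar, recycled).
#' @param flavor `"ct"` or `"pet"`.
#' @return An `image_volume` / `voi_mask` object.
#' @export
image_volume <- function(values, spacing = 2.344, flavor = c("ct", "pet")) {
  flavor <- match.arg(flavor)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(!is.finite(values))) stop("voxel values must be finite")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 in all axes")
  structure(list(values = values, spacing = spacing, flavor = flavor),
            class = "image_volume")
}

#' @rdname image_volume
#' @param mask Logical 3D array.
#' @export
voi_mask <- function(mask, spacing = 2.344) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  storage.mode(mask) <- "logical"
  if (any(is.na(mask))) stop("mask must not contain NA")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 in all axes")
  structure(list(mask = mask, spacing = spacing), class = "voi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image volume (%s): %s voxels, spacing %s mm\n", x$flavor,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("VOI mask: %d of %s voxels, %.3g mL\n", sum(x$mask),
              paste(dim(x$mask), collapse = "x"), mask_volume_ml(x)))
  invisible(x)
}

voxel_volume_mm3 <- function(x) prod(x$spacing)

#' VOI volume in millilitres
#'
#' @param mask A [voi_mask].
#' @return `n_voxels * voxel_volume_mm3 / 1000`.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$mask) * voxel_volume_mm3(mask) / 1000
}

check_aligned <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$mask)))
    stop("alignment error: volume and mask shapes differ")
  if (max(abs(vol$spacing - mask$spacing)) > 1e-9)
    stop("alignment error: volume and mask spacing differ")
  invisible(TRUE)
}

#' Restrict a seed VOI to adipose-tissue CT densities
#'
#' Keeps only seed voxels whose CT radiodensity lies in the adipose window
#' of -190 to -30 HU (closed interval on both ends).
#'
#' @param ct A CT [image_volume].
#' @param seed_mask A [voi_mask] aligned to `ct`.
#' @param hu_range Closed HU window, default `c(-190, -30)`.
#' @return A [voi_mask] equal to `seed_mask & (hu_range[1] <= HU <= hu_range[2])`.
#' @export
adipose_hu_mask <- function(ct, seed_mask, hu_range = c(-190, -30)) {
  stopifnot(inherits(ct, "image_volume"), inherits(seed_mask, "voi_mask"),
            length(hu_range) == 2L, hu_range[1] <= hu_range[2])
  if (ct$flavor != "ct") stop("adipose_hu_mask needs a CT volume")
  check_aligned(ct, seed_mask)
  keep <- seed_mask$mask & ct$values >= hu_range[1] &
    ct$values <= hu_range[2]
  voi_mask(keep, ct$spacing)
}

# Percentile by linear interpolation between closest ranks (stats type 7),
# stated explicitly so the spill-over rule is reproducible.
voi_percentile <- function(values, p) {
  unname(stats::quantile(values, probs = p / 100, type = 7, names = FALSE))
}

#' Exclude PET spill-over voxels from a VOI
#'
#' Removes in-mask voxels whose PET value exceeds the given percentile of
#' the in-mask value distribution — a guard against activity spilling in
#' from adjacent skeletal muscle or other hot tissue. Voxels strictly above
#' the threshold are dropped; ties at the threshold are kept.
#'
#' @param pet A PET [image_volume].
#' @param mask A [voi_mask] aligned to `pet`.
#' @param percentile Exclusion percentile in (0, 100); default 97.5.
#' @return The pruned [voi_mask].
#' @export
spillover_exclusion <- function(pet, mask, percentile = 97.5) {
  stopifnot(inherits(pet, "image_volume"), inherits(mask, "voi_mask"))
  if (pet$flavor != "pet") stop("spillover_exclusion needs a PET volume")
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100)
    stop("configuration error: percentile must be in (0, 100)")
  check_aligned(pet, mask)
  if (!any(mask$mask)) stop("empty-VOI error: mask has no voxels")
  vals <- pet$values[mask$mask]
  thr <- voi_percentile(vals, percentile)
  keep <- mask$mask & pet$values <= thr
  voi_mask(keep, pet$spacing)
}

#' The static SUV reconstruction window
#'
#' A single frame from minute 4 to minute 14 post-injection is used for
#' SUV quantification: late enough to avoid the early vascular phase, early
#' enough to avoid the late rise of skeletal-muscle uptake.
#'
#' @param start_min,end_min Window boundaries in minutes.
#' @return List with `start_min`, `end_min`, `duration_min`.
#' @export
suv_window <- function(start_min = 4, end_min = 14) {
  stopifnot(end_min > start_min)
  list(start_min = start_min, end_min = end_min,
       duration_min = end_min - start_min)
}

#' SUV, radiodensity and volume statistics over a VOI
#'
#' Computes the mean standardized uptake value (g/mL), mean CT radiodensity
#' (HU), volume (mL) and voxel count over a mask. SUV normalizes tissue
#' concentration by injected dose per body weight:
#' `SUV = mean(PET kBq/mL) / (dose_MBq / weight_kg in kBq/g)`.
#'
#' @param pet_static Static-window PET [image_volume] (kBq/mL).
#' @param ct CT [image_volume] (HU).
#' @param mask A [voi_mask] aligned to both volumes.
#' @param dose_MBq Injected activity, MBq (> 0).
#' @param weight_kg Body weight, kg (> 0).
#' @param min_volume_ml Minimum admissible VOI volume, mL (default 5.0).
#' @param allow_small Set `TRUE` to override the volume floor.
#' @param window The SUV acquisition window designation ([suv_window()]).
#' @return A list of class `voi_stats`: `suv_mean`, `radiodensity_mean`,
#'   `volume_ml`, `n_voxels`, and the `window` metadata.
#' @export
voi_stats <- function(pet_static, ct, mask, dose_MBq, weight_kg,
                      min_volume_ml = 5.0, allow_small = FALSE,
                      window = suv_window()) {
  stopifnot(inherits(pet_static, "image_volume"),
            inherits(ct, "image_volume"), inherits(mask, "voi_mask"))
  if (pet_static$flavor != "pet" || ct$flavor != "ct")
    stop("voi_stats needs a PET volume and a CT volume")
  if (!is.numeric(dose_MBq) || dose_MBq <= 0) stop("dose_MBq must be > 0")
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop("weight_kg must be > 0")
  check_aligned(pet_static, mask)
  check_aligned(ct, mask)
  if (!any(mask$mask)) stop("empty-VOI error: mask has no voxels")
  vol_ml <- mask_volume_ml(mask)
  if (vol_ml < min_volume_ml && !allow_small)
    stop(sprintf("VOI-too-small error: %.3g mL < %.3g mL floor",
                 vol_ml, min_volume_ml))
  # dose/weight in kBq/g: MBq*1000 kBq over kg*1000 g
  dose_per_weight <- dose_MBq / weight_kg
  structure(list(suv_mean = mean(pet_static$values[mask$mask]) /
                   dose_per_weight,
                 radiodensity_mean = mean(ct$values[mask$mask]),
                 volume_ml = vol_ml,
                 n_voxels = sum(mask$mask),
                 window = window),
            class = "voi_stats")
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf(
    "VOI statistics (SUV window %g-%g min)\n  SUV_mean = %.4g g/mL\n  radiodensity = %.4g HU\n  volume = %.4g mL (%d voxels)\n",
    x$window$start_min, x$window$end_min, x$suv_mean,
    x$radiodensity_mean, x$volume_ml, x$n_voxels))
  invisible(x)
}

#' Extract a time-activity curve from a dynamic PET series
#'
#' Averages each frame volume over the mask, yielding a frame-wise [tac]
#' with mid-frame timestamps — the measured-TAC input of [fit_tac()].
#'
#' @param frames List of PET [image_volume]s, one per frame, all aligned.
#' @param mask A [voi_mask].
#' @param schedule The [frame_schedule]; length must match `frames`.
#' @return A [tac].
#' @export
extract_tac <- function(frames, mask, schedule) {
  stopifnot(is.list(frames), inherits(mask, "voi_mask"),
            inherits(schedule, "frame_schedule"))
  if (length(frames) != n_frames(schedule))
    stop("schedule error: one volume per frame required")
  if (!any(mask$mask)) stop("empty-VOI error: mask has no voxels")
  vals <- vapply(frames, function(v) {
    stopifnot(inherits(v, "image_volume"))
    if (v$flavor != "pet") stop("extract_tac needs PET volumes")
    check_aligned(v, mask)
    mean(v$values[mask$mask])
  }, numeric(1))
  tac(schedule, vals)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti. Masks are stored as 0/1 integer volumes and
#' re-thresholded at 0.5 on read.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param flavor `"ct"` or `"pet"` for `read_volume`.
#' @return `read_volume` returns an [image_volume]; `read_mask` a
#'   [voi_mask]; writers return `path` invisibly.
#' @export
read_volume <- function(path, flavor = c("ct", "pet")) {
  flavor <- match.arg(flavor)
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               spacing = RNifti::pixdim(img)[1:3], flavor = flavor)
}

#' @rdname read_volume
#' @param vol An [image_volume] or [voi_mask] to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img) > 0.5, dim = dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_mask <- function(vol, path) {
  stopifnot(inherits(vol, "voi_mask"))
  img <- RNifti::asNifti(array(as.integer(vol$mask), dim = dim(vol$mask)))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
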