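# Containers and I/O: multichannel 3-D stacks as multi-page TIFF with a JSON
# sidecar, per-centriole annotations (CSV or JSON), and ground-truth records.
#
# File coordinate convention: voxel-indexed, 0-based, (x, y, z) with x the
# fastest axis.  In-memory objects use R's native 1-based indexing; readers
# and writers convert.

#' Construct a multichannel 3-D image stack
#'
#' @param voxels 4-D numeric array indexed `[x, y, z, channel]` (a 3-D array
#'   is promoted to a single channel); intensities must be finite and >= 0.
#' @param pitch_lateral_nm expanded-space lateral voxel size (nm); identical
#'   for x and y.  `NA` marks an unknown pitch: nm-valued operations refuse
#'   such stacks.
#' @param pitch_axial_nm expanded-space axial voxel size (nm).
#' @param channel_roles character vector of role labels (`wall`, `marker`,
#'   `reference`, `appendage`, `center`, `unknown`), one per channel.
#' @param view_convention `"distal"` (observer at the distal end;
#'   counterclockwise azimuths positive) or `"proximal"`.
#' @param expansion_factor optional gel expansion coefficient carried as
#'   metadata.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, pitch_lateral_nm = NA_real_,
                        pitch_axial_nm = NA_real_,
                        channel_roles = NULL,
                        view_convention = c("distal", "proximal"),
                        expansion_factor = NA_real_) {
  view_convention <- match.arg(view_convention)
  if (length(dim(voxels)) == 3) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4)
    .stopf("voxels must be a 3-D or 4-D array, got %d dims", length(dim(voxels)))
  if (any(!is.finite(voxels)) || any(voxels < 0))
    .stopf("stack intensities must be finite and >= 0")
  nc <- dim(voxels)[4]
  if (is.null(channel_roles)) channel_roles <- rep("unknown", nc)
  if (length(channel_roles) != nc)
    .stopf("channel_roles length %d != %d channels", length(channel_roles), nc)
  structure(list(voxels = voxels,
                 pitch_lateral_nm = as.numeric(pitch_lateral_nm),
                 pitch_axial_nm = as.numeric(pitch_axial_nm),
                 channel_roles = as.character(channel_roles),
                 view_convention = view_convention,
                 expansion_factor = as.numeric(expansion_factor)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], paste(x$channel_roles, collapse = ", ")))
  cat(sprintf("  pitch %s nm lateral / %s nm axial, %s view, expansion %s\n",
              format(x$pitch_lateral_nm), format(x$pitch_axial_nm),
              x$view_convention, format(x$expansion_factor)))
  invisible(x)
}

# index of the first channel with a given role (error if absent)
.channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1 || ch > dim(stack$voxels)[4])
      .stopf("channel index %d out of range", ch)
    return(ch)
  }
  ch <- match(channel, stack$channel_roles)
  if (is.na(ch)) .stopf("no channel with role '%s' in stack [%s]",
                        channel, paste(stack$channel_roles, collapse = ", "))
  ch
}

.require_pitch <- function(stack, what = "this operation") {
  if (!is.finite(stack$pitch_lateral_nm) || !is.finite(stack$pitch_axial_nm))
    .stopf("%s requires a known voxel pitch; this stack has none", what)
  invisible(TRUE)
}

#' Write a stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are channel-major (all z planes of channel 1, then channel 2, ...).
#' Intensities are stored as 16-bit samples scaled by a per-file
#' `intensity_scale` recorded in the sidecar; data already on that 16-bit
#' grid round-trips exactly, arbitrary values within `scale / 65535`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    # snap onto the 16-bit grid before handing to the TIFF writer so the
    # stored code is deterministic (page rows = y)
    pages[[k]] <- round(t(stack$voxels[, , z, ch]) / scale * 65535) / 65535
    k <- k + 1L
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "none"),
                 error = function(e) .stopf("cannot write TIFF '%s': %s",
                                            path, conditionMessage(e)))
  meta <- list(format = "ninefold-stack", version = 1L,
               dim = d, intensity_scale = scale,
               pitch_lateral_nm = stack$pitch_lateral_nm,
               pitch_axial_nm = stack$pitch_axial_nm,
               channel_roles = stack$channel_roles,
               view_convention = stack$view_convention,
               expansion_factor = stack$expansion_factor)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' Without a sidecar the pages are loaded as a single-channel z-stack with
#' unknown pitch (a warning is emitted); operations that need nm units will
#' refuse such stacks.
#'
#' @param path TIFF path.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) .stopf("unreadable TIFF '%s': %s",
                                               path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), shp))
      .stopf("inconsistent page shapes in '%s' at page %d", path, i)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    d <- as.integer(meta$dim)
    if (prod(d[3:4]) != length(pages))
      .stopf("sidecar of '%s' declares %d pages, file has %d",
             path, prod(d[3:4]), length(pages))
    vox <- array(0, d)
    k <- 1L
    for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
      vox[, , z, ch] <- t(pages[[k]]) * meta$intensity_scale
      k <- k + 1L
    }
    image_stack(vox, meta$pitch_lateral_nm, meta$pitch_axial_nm,
                meta$channel_roles, meta$view_convention,
                if (is.null(meta$expansion_factor)) NA_real_ else meta$expansion_factor)
  } else {
    .warnf("no sidecar for '%s': loading as single-channel stack with unknown pitch",
           path)
    vox <- array(0, c(shp[2], shp[1], length(pages), 1L))
    for (z in seq_along(pages)) vox[, , z, 1] <- t(pages[[z]])
    image_stack(vox, NA_real_, NA_real_, "unknown", "distal")
  }
}

#' Construct a per-centriole annotation
#'
#' Landmarks replacing the interactive annotation step: ring points on the
#' triplet circle, a rotational reference (a point or a directive), the long
#' axis, and the axial frame.  Except for `axis_points` (original stack),
#' all point coordinates refer to the verticalized stack.
#'
#' @param particle_id identifier string.
#' @param ring_points matrix (>= 3 rows) of `(x, y)` voxel coordinates on one
#'   transverse plane, marking the triplet ring; must be non-collinear.
#' @param reference_point length-3 `(x, y, z)` voxel point for rotational
#'   registration, or `NULL` when `reference_mode = "brightest"`.
#' @param reference_mode one of `"point"`, `"brightest"`,
#'   `"basal_foot_point"`, `"c_end_point"`.
#' @param axis_points 2 x 3 matrix of `(x, y, z)` voxel points on the long
#'   axis of the original stack, proximal row first.
#' @param z_frame `(z_proximal, z_distal)` plane indices bounding the
#'   centriole in the verticalized stack; may be fractional.
#' @param expansion_factor gel expansion coefficient (> 1).
#' @param view_convention `"distal"` or `"proximal"`.
#' @return an object of class `centriole_annotation`.
#' @export
centriole_annotation <- function(particle_id, ring_points,
                                 reference_point = NULL,
                                 reference_mode = c("point", "brightest",
                                                    "basal_foot_point",
                                                    "c_end_point"),
                                 axis_points = NULL, z_frame,
                                 expansion_factor,
                                 view_convention = c("distal", "proximal")) {
  reference_mode <- match.arg(reference_mode)
  view_convention <- match.arg(view_convention)
  ann <- structure(list(particle_id = as.character(particle_id),
                        ring_points = as.matrix(ring_points),
                        reference_point = if (is.null(reference_point)) NULL
                                          else as.numeric(reference_point),
                        reference_mode = reference_mode,
                        axis_points = if (is.null(axis_points)) NULL
                                      else as.matrix(axis_points),
                        z_frame = as.numeric(z_frame),
                        expansion_factor = as.numeric(expansion_factor),
                        view_convention = view_convention),
                   class = "centriole_annotation")
  validate_annotation(ann)
  ann
}

#' Validate an annotation record
#'
#' Checks every invariant and reports violations with the particle id and
#' field name.
#'
#' @param ann a `centriole_annotation`.
#' @return the annotation, invisibly.
#' @export
validate_annotation <- function(ann) {
  id <- ann$particle_id
  fail <- function(field, msg)
    .stopf("annotation '%s', field %s: %s", id, field, msg)
  rp <- ann$ring_points
  if (is.null(rp) || nrow(rp) < 3)
    fail("ring_points", sprintf("ring_points >= 3 required (got %d)",
                                if (is.null(rp)) 0L else nrow(rp)))
  cen <- colMeans(rp[, 1:2, drop = FALSE])
  sv <- svd(sweep(rp[, 1:2, drop = FALSE], 2, cen))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    fail("ring_points", "degenerate ring (collinear points)")
  if (length(ann$z_frame) != 2 || !(ann$z_frame[1] < ann$z_frame[2]))
    fail("z_frame", "z_proximal < z_distal required")
  if (!is.finite(ann$expansion_factor) || ann$expansion_factor <= 1)
    fail("expansion_factor", "must be > 1")
  if (ann$reference_mode != "brightest" && is.null(ann$reference_point))
    fail("reference_point", sprintf("required for reference_mode '%s'",
                                    ann$reference_mode))
  if (!is.null(ann$reference_point) && length(ann$reference_point) != 3)
    fail("reference_point", "must be (x, y, z)")
  if (!is.null(ann$axis_points) &&
      (nrow(ann$axis_points) != 2 || ncol(ann$axis_points) != 3))
    fail("axis_points", "must be a 2 x 3 matrix")
  invisible(ann)
}

.ann_to_list <- function(ann) {
  list(particle_id = ann$particle_id,
       ring_points = unname(apply(ann$ring_points, 1, function(r) r - 1,
                                  simplify = FALSE)),
       reference_point = if (is.null(ann$reference_point)) NULL
                         else ann$reference_point - 1,
       reference_mode = ann$reference_mode,
       axis_points = if (is.null(ann$axis_points)) NULL
                     else unname(apply(ann$axis_points, 1, function(r) r - 1,
                                       simplify = FALSE)),
       z_frame = ann$z_frame - 1,
       expansion_factor = ann$expansion_factor,
       view_convention = ann$view_convention)
}

.ann_from_list <- function(x) {
  centriole_annotation(
    particle_id = x$particle_id,
    ring_points = do.call(rbind, lapply(x$ring_points, as.numeric)) + 1,
    reference_point = if (is.null(x$reference_point)) NULL
                      else as.numeric(x$reference_point) + 1,
    reference_mode = x$reference_mode,
    axis_points = if (is.null(x$axis_points)) NULL
                  else do.call(rbind, lapply(x$axis_points, as.numeric)) + 1,
    z_frame = as.numeric(x$z_frame) + 1,
    expansion_factor = x$expansion_factor,
    view_convention = x$view_convention)
}

#' Write annotations to JSON or CSV
#'
#' JSON holds one record per annotation; CSV has one row per particle with
#' point lists JSON-encoded in their cells.  File coordinates are 0-based.
#'
#' @param annotations a list of `centriole_annotation` objects.
#' @param path output path ending in `.json` or `.csv`.
#' @return the path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(annotations, .ann_to_list)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", pretty = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(particle_id = r$particle_id,
                 ring_points = as.character(jsonlite::toJSON(r$ring_points, digits = I(17))),
                 reference_point = as.character(jsonlite::toJSON(r$reference_point, digits = I(17), null = "null")),
                 reference_mode = r$reference_mode,
                 axis_points = as.character(jsonlite::toJSON(r$axis_points, digits = I(17), null = "null")),
                 z_frame = as.character(jsonlite::toJSON(r$z_frame, digits = I(17))),
                 expansion_factor = r$expansion_factor,
                 view_convention = r$view_convention,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else .stopf("annotation path must end in .json or .csv: %s", path)
  invisible(path)
}

#' Load annotations from JSON or CSV
#'
#' Readers are strict: malformed fields are rejected with the particle id
#' and field named, never coerced silently.
#'
#' @param path annotation file (`.json` or `.csv`).
#' @return a list of `centriole_annotation` objects.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) {
      list(particle_id = df$particle_id[i],
           ring_points = jsonlite::fromJSON(df$ring_points[i], simplifyVector = FALSE),
           reference_point = if (df$reference_point[i] %in% c("null", "", NA)) NULL
                             else jsonlite::fromJSON(df$reference_point[i]),
           reference_mode = df$reference_mode[i],
           axis_points = if (df$axis_points[i] %in% c("null", "", NA)) NULL
                         else jsonlite::fromJSON(df$axis_points[i], simplifyVector = FALSE),
           z_frame = jsonlite::fromJSON(df$z_frame[i]),
           expansion_factor = df$expansion_factor[i],
           view_convention = df$view_convention[i])
    })
  } else .stopf("annotation path must end in .json or .csv: %s", path)
  lapply(recs, .ann_from_list)
}

#' Export generator ground truth as an annotation
#'
#' Builds the landmark record a human annotator would have produced, from
#' the generative geometry: ring points at the true triplet positions on the
#' mid-plane of the verticalized frame, the reference point at the marker
#' centroid (or basal foot), the true axis, and the true axial frame.  This
#' lets the full standardization chain run with zero manual input.
#'
#' @param truth a `ground_truth` record.
#' @param reference one of `"marker"` (marker centroid azimuth, mode
#'   `"point"`) , `"brightest"` (no point; image-driven registration) or
#'   `"basal_foot"` (basal-foot azimuth, mode `"basal_foot_point"`).
#' @return a `centriole_annotation`.
#' @export
annotations_from_truth <- function(truth,
                                   reference = c("marker", "brightest",
                                                 "basal_foot")) {
  reference <- match.arg(reference)
  p <- truth$params
  rot <- p$rotation_deg
  cen <- truth$ring_center_vox
  rv <- truth$ring_radius_vox
  az <- .deg2rad(norm_angle(truth$triplet_azimuths_deg + rot))
  ring <- cbind(cen[1] + rv * cos(az), cen[2] + rv * sin(az))
  zmid <- mean(truth$z_range)
  zref <- truth$z_range[1] + 0.9 * diff(range(truth$z_range))
  if (reference == "marker") {
    a <- .deg2rad(norm_angle(truth$marker_centroid_azimuth_deg + rot))
    rp <- c(cen[1] + p$marker_radial_fraction * rv * cos(a),
            cen[2] + p$marker_radial_fraction * rv * sin(a), zref)
    mode <- "point"
  } else if (reference == "basal_foot") {
    if (!isTRUE(p$basal_foot)) .stopf("truth has no basal foot channel")
    a <- .deg2rad(norm_angle(p$marker_azimuth_deg + 180 -
                               p$basal_foot_azimuth_offset_deg + rot))
    rp <- c(cen[1] + 1.5 * rv * cos(a), cen[2] + 1.5 * rv * sin(a), zmid)
    mode <- "basal_foot_point"
  } else {
    rp <- NULL
    mode <- "brightest"
  }
  ctr <- (truth$dims + 1) / 2
  ax <- truth$axis_vector
  axis_pts <- rbind(ctr - 5 * ax / c(1, 1, p$voxel_pitch_axial_nm / p$voxel_pitch_nm),
                    ctr + 5 * ax / c(1, 1, p$voxel_pitch_axial_nm / p$voxel_pitch_nm))
  centriole_annotation(
    particle_id = if (is.null(truth$particle_id)) "truth" else truth$particle_id,
    ring_points = ring, reference_point = rp, reference_mode = mode,
    axis_points = axis_pts, z_frame = truth$z_range,
    expansion_factor = p$expansion_factor, view_convention = "distal")
}

#' Write / read ground truth as JSON
#'
#' The serialization is lossless: numeric fields are written at full
#' precision and restored exactly.
#'
#' @param truth a `ground_truth` record.
#' @param path JSON path.
#' @return `write_ground_truth`: the path, invisibly; `read_ground_truth`:
#'   the `ground_truth` record.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x$params$dims)) x$params$dims <- as.integer(x$params$dims)
  else x$params["dims"] <- list(NULL)
  x$params$n_triplets <- as.integer(x$params$n_triplets)
  x$params$seed <- as.integer(x$params$seed)
  x$params$translation_nm <- as.numeric(x$params$translation_nm)
  x$seed <- as.integer(x$seed)
  x$dims <- as.integer(x$dims)
  x$warnings <- as.character(x$warnings)
  names(x$z_range) <- c("proximal", "distal")
  names(x$channel_peaks) <- .channel_roles(x$params)
  structure(x, class = "ground_truth")
}

#' Cohort-level ground-truth index
#'
#' @param cohort a list returned by [generate_cohort()].
#' @param path optional CSV path; when given the table is also written.
#' @return a data.frame with one row per particle (id, marker azimuth,
#'   procentriole azimuth if any, length, expansion factor, seed).
#' @export
cohort_index <- function(cohort, path = NULL) {
  df <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    tr <- cohort[[i]]$truth
    data.frame(
      particle_id = if (is.null(tr$particle_id)) sprintf("p%03d", i) else tr$particle_id,
      marker_azimuth_deg = tr$params$marker_azimuth_deg,
      procentriole_azimuth_deg = if (is.null(tr$procentriole_azimuth_deg))
        NA_real_ else tr$procentriole_azimuth_deg,
      length_nm = tr$params$centriole_length_nm,
      expansion_factor = tr$params$expansion_factor,
      seed = tr$seed, stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
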