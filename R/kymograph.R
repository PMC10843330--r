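#' Space-time kymograph of an ablated cell's membranes
#'
#' A kymograph samples image intensity along a line drawn perpendicular to a
#' linear laser cut, one column per movie frame: rows are spatial positions
#' (row 1 = proximal/anterior end of the line), columns are frames. The two
#' bright ridges are the membranes of the ablated cell; frames acquired
#' while the cutting laser fires are dark (the "ablation gap").
#'
#' @param intensity numeric matrix in \[0, 1\]; rows = space, cols = frames.
#' @param pixel_size spatial sampling (um/pixel, > 0).
#' @param frame_interval temporal sampling (s/frame, > 0); default 0.09.
#' @param ablation_start_index,ablation_end_index first and last dark frame
#'   (1-based column indices).
#' @param gap_duration duration of the unobserved ablation interval (s);
#'   default 0.65, the first observed timepoint after ablation.
#' @return An object of class `kymograph`.
#' @seealso [generate_kymograph()], [track_membranes()]
#' @export
kymograph <- function(intensity, pixel_size, frame_interval = 0.09,
                      ablation_start_index, ablation_end_index,
                      gap_duration = 0.65) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(intensity)) || min(intensity) < 0 || max(intensity) > 1)
    stop("`intensity` must be finite and within [0, 1]", call. = FALSE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  stopifnot_scalar(gap_duration, "gap_duration", positive = TRUE)
  a0 <- as.integer(ablation_start_index); a1 <- as.integer(ablation_end_index)
  if (!(a0 >= 1 && a0 < a1 && a1 < ncol(intensity)))
    stop("need ablation_start_index < ablation_end_index < n_frames", call. = FALSE)
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 ablation_start_index = a0, ablation_end_index = a1,
                 gap_duration = gap_duration),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d px x %d frames (%.3g um/px, %.3g s/frame)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              x$frame_interval))
  cat(sprintf("  ablation gap: frames %d-%d (%.3g s)\n",
              x$ablation_start_index, x$ablation_end_index, x$gap_duration))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$intensity)

#' Synthesize a kymograph of post-ablation membrane recoil
#'
#' Renders two Gaussian-profile membrane ridges symmetric about the ablation
#' line whose separation grows by the closed-form recoil
#' [displacement()]`(t, params)`, split equally between the two membranes.
#' Frames inside the ablation gap are dark. Background noise and per-ridge
#' intensity jitter are Gaussian; the output is a pure function of the
#' arguments and `seed`.
#'
#' @param params a [relaxation_params()] object (ground truth dynamics).
#' @param bond_distance pre-ablation membrane separation (um).
#' @param membrane_width Gaussian sigma of each membrane ridge (um).
#' @param noise_sd additive background noise sd (intensity units).
#' @param intensity_jitter sd of per-frame multiplicative ridge amplitude
#'   jitter.
#' @param pixel_size um per pixel; default 0.2.
#' @param frame_interval s per frame; default 0.09.
#' @param n_pre number of pre-ablation frames; default 10.
#' @param duration total post-ablation observation time (s); default 60.
#' @param gap_duration dark-gap duration (s); default 0.65.
#' @param peak_intensity ridge peak intensity; default 0.8.
#' @param n_rows optional fixed image height in pixels; by default the field
#'   of view is sized to contain the full recoil. An explicit `n_rows` too
#'   small to contain it is rejected.
#' @param seed RNG seed (required).
#' @return A [kymograph()] whose `ground_truth` attribute stores `params`,
#'   `bond_distance` and the per-frame true separation.
#' @export
generate_kymograph <- function(params, bond_distance = 3, membrane_width = 0.3,
                               noise_sd = 0.02, intensity_jitter = 0.05,
                               pixel_size = 0.2, frame_interval = 0.09,
                               n_pre = 10, duration = 60, gap_duration = 0.65,
                               peak_intensity = 0.8, n_rows = NULL, seed) {
  stopifnot(inherits(params, "relaxation_params"))
  stopifnot_scalar(bond_distance, "bond_distance", positive = TRUE)
  stopifnot_scalar(membrane_width, "membrane_width", positive = TRUE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  x_total <- params$X_f + params$X_s
  margin <- 4 * membrane_width + 1
  if (is.null(n_rows))
    n_rows <- ceiling((bond_distance + x_total + 2 * margin) / pixel_size)
  if ((bond_distance + x_total) / 2 + 3 * membrane_width >= n_rows * pixel_size / 2)
    stop("displacement exceeds spatial field of view", call. = FALSE)
  center <- n_rows / 2 * pixel_size

  n_gap <- max(1L, round(gap_duration / frame_interval))
  n_post <- max(2L, floor((duration - gap_duration) / frame_interval) + 1L)
  n_frames <- n_pre + n_gap + n_post
  # model time per frame: 0 during pre-ablation; gap frames unobserved;
  # post frames at gap_duration + j * frame_interval
  t_post <- gap_duration + (seq_len(n_post) - 1L) * frame_interval
  sep <- c(rep(bond_distance, n_pre), rep(NA_real_, n_gap),
           bond_distance + displacement(t_post, params))

  z <- (seq_len(n_rows) - 0.5) * pixel_size
  img <- matrix(0, n_rows, n_frames)
  with_seed(seed, {
    for (j in seq_len(n_frames)) {
      if (is.na(sep[j])) next  # dark gap frame
      amp <- peak_intensity * (1 + rnorm(2, 0, intensity_jitter))
      c_up <- center - sep[j] / 2
      c_lo <- center + sep[j] / 2
      img[, j] <- amp[1] * exp(-(z - c_up)^2 / (2 * membrane_width^2)) +
        amp[2] * exp(-(z - c_lo)^2 / (2 * membrane_width^2))
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                          n_rows, n_frames)
  })
  img <- pmin(pmax(img, 0), 1)
  out <- kymograph(img, pixel_size = pixel_size, frame_interval = frame_interval,
                   ablation_start_index = n_pre + 1L,
                   ablation_end_index = n_pre + n_gap,
                   gap_duration = gap_duration)
  attr(out, "ground_truth") <- list(params = params,
                                    bond_distance = bond_distance,
                                    separation = sep, center = center)
  out
}

#' Preprocess a kymograph (Gaussian blur, sigma = 1 pixel)
#'
#' Smooths the intensity image with an isotropic Gaussian of one pixel
#' standard deviation before ridge tracking; geometry metadata is unchanged.
#'
#' @param kym a [kymograph()].
#' @param sigma blur standard deviation in pixels; default 1.
#' @return The blurred [kymograph()].
#' @export
preprocess_kymograph <- function(kym, sigma = 1) {
  stopifnot(inherits(kym, "kymograph"))
  gt <- attr(kym, "ground_truth")
  img <- EBImage::gblur(kym$intensity, sigma = sigma)
  img <- pmin(pmax(img, 0), 1)
  out <- kymograph(img, kym$pixel_size, kym$frame_interval,
                   kym$ablation_start_index, kym$ablation_end_index,
                   kym$gap_duration)
  attr(out, "ground_truth") <- gt
  out
}

#' Track the two membrane ridges through a kymograph
#'
#' Deterministic per-frame ridge detection: intensity maxima above an
#' Otsu-derived threshold, refined to sub-pixel precision by a parabolic fit
#' through the log-intensity of the peak and its neighbours (exact for the
#' Gaussian ridge profiles of fluorescent membranes, which remain Gaussian
#' under the preprocessing blur), then linked across frames by
#' nearest-neighbour continuity (each frame's upper/lower ridge is the
#' candidate closest to the previous frame's position on the same side of
#' the ablation line). Dark gap frames carry no positions. Frames with
#' fewer than two detectable ridges are flagged and filled by linear
#' interpolation from neighbouring frames; more than 30% flagged frames is a
#' hard failure.
#'
#' @param kym a preprocessed [kymograph()] with at least one frame on each
#'   side of the ablation gap.
#' @return An object of class `membrane_track`: list with `frame_indices`
#'   (observed frames), `upper`, `lower` (ridge positions, um from row 0),
#'   and `quality` (1 = detected, 0 = interpolated).
#' @export
track_membranes <- function(kym) {
  stopifnot(inherits(kym, "kymograph"))
  img <- kym$intensity
  n_frames <- ncol(img)
  a0 <- kym$ablation_start_index; a1 <- kym$ablation_end_index
  if (a0 < 2 || a1 >= n_frames)
    stop("need at least one frame before and after the ablation gap", call. = FALSE)
  observed <- setdiff(seq_len(n_frames), a0:a1)
  thr <- EBImage::otsu(img[, observed, drop = FALSE], range = c(0, 1))

  first_peaks <- frame_peaks(img[, observed[1]], thr, kym$pixel_size)
  if (length(first_peaks) < 2)
    stop("cannot resolve two membranes in the first frame", call. = FALSE)
  ord <- order(-frame_peak_heights(img[, observed[1]], first_peaks, kym$pixel_size))
  two <- sort(first_peaks[ord[1:2]])
  if (diff(two) < 2 * kym$pixel_size)
    stop("membranes closer than 2 px; unresolvable", call. = FALSE)
  ref_mid <- mean(two)

  upper <- lower <- rep(NA_real_, length(observed))
  quality <- rep(0, length(observed))
  prev_up <- two[1]; prev_lo <- two[2]
  for (i in seq_along(observed)) {
    pk <- frame_peaks(img[, observed[i]], thr, kym$pixel_size)
    up_cand <- pk[pk < ref_mid]
    lo_cand <- pk[pk >= ref_mid]
    if (length(up_cand) >= 1 && length(lo_cand) >= 1) {
      upper[i] <- up_cand[which.min(abs(up_cand - prev_up))]
      lower[i] <- lo_cand[which.min(abs(lo_cand - prev_lo))]
      if (lower[i] > upper[i]) {
        quality[i] <- 1
        prev_up <- upper[i]; prev_lo <- lower[i]
      } else upper[i] <- lower[i] <- NA_real_
    }
  }
  n_flagged <- sum(quality == 0)
  if (n_flagged > 0.3 * length(observed))
    stop(sprintf("membrane tracking failed on %d/%d frames (> 30%%)",
                 n_flagged, length(observed)), call. = FALSE)
  if (n_flagged > 0) {  # fill flagged frames from neighbours
    ok <- quality == 1
    upper[!ok] <- approx(observed[ok], upper[ok], xout = observed[!ok],
                         rule = 2)$y
    lower[!ok] <- approx(observed[ok], lower[ok], xout = observed[!ok],
                         rule = 2)$y
  }
  structure(list(frame_indices = observed, upper = upper, lower = lower,
                 quality = quality),
            class = "membrane_track")
}

# Sub-pixel peak positions (um) of local maxima above `thr` in one column.
# Refinement: parabola through log intensity at (i-1, i, i+1); exact for a
# noiseless Gaussian ridge.
frame_peaks <- function(col, thr, pixel_size) {
  n <- length(col)
  if (n < 3) return(numeric(0))
  i <- which(col[-c(1, n)] >= col[-c(n - 1, n)] &
               col[-c(1, n)] >= col[-c(1, 2)] &
               col[-c(1, n)] > thr) + 1L
  if (!length(i)) return(numeric(0))
  l0 <- log(pmax(col[i - 1L], 1e-12))
  l1 <- log(pmax(col[i], 1e-12))
  l2 <- log(pmax(col[i + 1L], 1e-12))
  denom <- l0 - 2 * l1 + l2
  offset <- ifelse(abs(denom) > .Machine$double.eps,
                   0.5 * (l0 - l2) / denom, 0)
  offset <- pmin(pmax(offset, -0.5), 0.5)
  pos <- sort((i + offset - 0.5) * pixel_size)
  # merge duplicates from tied adjacent pixels (same ridge found twice)
  if (length(pos) > 1) {
    grp <- cumsum(c(TRUE, diff(pos) > 0.75 * pixel_size))
    pos <- as.numeric(tapply(pos, grp, mean))
  }
  pos
}

frame_peak_heights <- function(col, positions_um, pixel_size) {
  col[pmin(pmax(round(positions_um / pixel_size + 0.5), 1), length(col))]
}

#' @export
print.membrane_track <- function(x, ...) {
  cat(sprintf("Membrane track: %d frames, %d interpolated\n",
              length(x$frame_indices), sum(x$quality == 0)))
  invisible(x)
}

#' Extract a displacement trace from a membrane track
#'
#' The pre-gap membrane separation defines the baseline bond distance; the
#' displacement at each post-gap frame is the current separation minus that
#' baseline. Times are measured from the first post-gap frame and the gap
#' duration is carried as the trace's `delta_t`. Decreasing steps are
#' tolerated (noise) but the trace is flagged `nonmonotone` when more than
#' 20% of steps decrease.
#'
#' @param track a [track_membranes()] result.
#' @param kym the [kymograph()] the track came from.
#' @return A [displacement_trace()]; attribute `flags` may contain
#'   `"nonmonotone"`.
#' @export
extract_displacement_trace <- function(track, kym) {
  stopifnot(inherits(track, "membrane_track"), inherits(kym, "kymograph"))
  sep <- track$lower - track$upper
  pre <- track$frame_indices < kym$ablation_start_index
  post <- track$frame_indices > kym$ablation_end_index
  if (!any(pre)) stop("no pre-gap baseline frames", call. = FALSE)
  baseline <- mean(sep[pre])
  dx <- sep[post] - baseline
  times <- (track$frame_indices[post] - min(track$frame_indices[post])) *
    kym$frame_interval
  tr <- displacement_trace(times, dx, delta_t = kym$gap_duration)
  steps <- diff(dx)
  if (length(steps) && mean(steps < 0) > 0.2)
    attr(tr, "flags") <- "nonmonotone"
  tr
}

#' Initial recoil velocity from a tracked kymograph
#'
#' The mean absolute displacement of the two membranes across the dark
#' ablation gap, divided by the gap duration (default 0.65 s). Because each
#' membrane moves half the bond displacement in a symmetric recoil, the
#' default `bond_displacement = TRUE` rescales by 2 so the estimate matches
#' the closed-form [initial_recoil_velocity()] defined on the full bond
#' displacement; set it to `FALSE` for the raw per-membrane convention.
#'
#' @inheritParams extract_displacement_trace
#' @param bond_displacement logical; rescale the per-membrane mean by 2
#'   (default `TRUE`).
#' @return Velocity in um/s.
#' @export
recoil_velocity_from_kymograph <- function(track, kym, bond_displacement = TRUE) {
  stopifnot(inherits(track, "membrane_track"), inherits(kym, "kymograph"))
  pre <- track$frame_indices < kym$ablation_start_index
  post <- track$frame_indices > kym$ablation_end_index
  if (!any(pre) || !any(post))
    stop("need at least one frame on each side of the gap", call. = FALSE)
  i_pre <- which(pre)[sum(pre)]
  i_post <- which(post)[1]
  d_up <- abs(track$upper[i_post] - track$upper[i_pre])
  d_lo <- abs(track$lower[i_post] - track$lower[i_pre])
  v <- mean(c(d_up, d_lo)) / kym$gap_duration
  if (bond_displacement) v <- 2 * v
  v
}

#' Read / write kymographs as TIFF plus JSON sidecar
#'
#' The intensity image is stored as a single-channel float TIFF; pixel size,
#' frame interval and ablation-gap bookkeeping travel in a JSON sidecar at
#' `<path>.json`.
#'
#' @param kym a [kymograph()].
#' @param path TIFF file path.
#' @return `write_kymograph()` returns `path` invisibly; `read_kymograph()`
#'   returns a [kymograph()].
#' @export
write_kymograph <- function(kym, path) {
  stopifnot(inherits(kym, "kymograph"))
  tiff::writeTIFF(kym$intensity, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = kym$pixel_size,
               frame_interval_s = kym$frame_interval,
               ablation_start_index = kym$ablation_start_index,
               ablation_end_index = kym$ablation_end_index,
               gap_duration_s = kym$gap_duration,
               axis_convention = "row 1 = proximal/anterior end of line")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  kymograph(img, pixel_size = meta$pixel_size_um,
            frame_interval = meta$frame_interval_s,
            ablation_start_index = meta$ablation_start_index,
            ablation_end_index = meta$ablation_end_index,
            gap_duration = meta$gap_duration_s)
}
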