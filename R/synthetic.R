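#' Genotype scenario: distributions behind the synthetic generators
#'
#' Bundles the per-genotype distributions every generator draws from. The
#' wild-type recoil parameters are truncated normals centred in the
#' measured ranges (fast displacement 1.8-2.6 um, slow displacement
#' 6-8 um, fast timescale ~0.65 s, slow timescale ~20 s). The `pk` genotype
#' differs from wild type only in the fast displacement: its fast elastic
#' constant is scaled by `kf_factor` (default 1.5) with the fast viscosity
#' scaled identically, so X_f shrinks by `1/kf_factor` while tau_f (and the
#' slow mode) are untouched.
#'
#' Adult-wing aspect-ratio pools use the measured pool sizes (wt 53, pk 47,
#' stbm 74, fmi 56). The wing-shape effect (pk and stbm slightly rounder
#' than wt, fmi indistinguishable) is encoded as a mean shift
#' `wing_effect` in aspect-ratio units; the default 0.065 (1.3 within-group
#' SDs of 0.05) is a calibrated, arbitrary constant chosen so that the
#' four-group Kruskal-Wallis test on the full pools is significant while
#' subsamples of 3 wings per genotype detect it only about a fifth of the
#' time.
#'
#' The elongation time course is an asymmetric Gaussian bump (rise width
#' shorter than decay width) sampled every 5 minutes, emulating blade-mean
#' cell elongation rising to a peak during the flows and relaxing after.
#'
#' @param kf_factor multiplicative change of the fast elastic constant in
#'   `pk` (viscosity co-scaled; timescale conserved); default 1.5.
#' @param wing_effect aspect-ratio mean shift of the rounder genotypes
#'   (pk, stbm) relative to wt/fmi; default 0.065.
#' @param overrides named list merged over the defaults for fine control.
#' @return An object of class `genotype_scenario`: nested list with one
#'   entry per genotype (`wt`, `pk`, `stbm`, `fmi`), each holding `relax`
#'   (mean/sd/bounds for X_f, X_s, tau_f, tau_s), `wing` (mean, sd, n) and
#'   `elongation` (peak_value, peak_time, rise_width, decay_width,
#'   noise_sd, t_start, t_end) settings.
#' @export
genotype_scenario <- function(kf_factor = 1.5, wing_effect = 0.065,
                              overrides = NULL) {
  stopifnot_scalar(kf_factor, "kf_factor", positive = TRUE)
  stopifnot_scalar(wing_effect, "wing_effect")
  # wt recoil parameters: centred on the measured ranges
  wt_relax <- list(
    X_f = list(mean = 2.2, sd = 0.2, lo = 1.8, hi = 2.6),    # um, measured range
    X_s = list(mean = 7.0, sd = 0.5, lo = 6.0, hi = 8.0),    # um, measured range
    tau_f = list(mean = 0.65, sd = 0.05, lo = 0.4, hi = 0.9),  # s
    tau_s = list(mean = 20, sd = 2, lo = 14, hi = 26))         # s
  pk_relax <- wt_relax
  # pk: kf (and eta_f) scaled by kf_factor => X_f scaled by 1/kf_factor,
  # tau_f conserved
  for (f in c("mean", "sd", "lo", "hi"))
    pk_relax$X_f[[f]] <- wt_relax$X_f[[f]] / kf_factor
  elong <- list(peak_value = 0.2,    # blade-mean elongation at peak (dimensionless)
                peak_time = 23,      # hAPF; calibrated, arbitrary
                rise_width = 5,      # h; mild skew: decay slower than rise
                decay_width = 7,     # h
                noise_sd = 0.005,
                t_start = 16, t_end = 39, dt = 5 / 60)  # imaged every 5 min
  wing_sd <- 0.05  # within-genotype SD of the aspect ratio; calibrated, arbitrary
  scen <- list(
    wt = list(relax = wt_relax, elongation = elong,
              wing = list(mean = 2.20, sd = wing_sd, n = 53)),
    pk = list(relax = pk_relax, elongation = elong,
              wing = list(mean = 2.20 - wing_effect, sd = wing_sd, n = 47)),
    stbm = list(relax = wt_relax, elongation = elong,
                wing = list(mean = 2.20 - wing_effect, sd = wing_sd, n = 74)),
    fmi = list(relax = wt_relax, elongation = elong,
               wing = list(mean = 2.20, sd = wing_sd, n = 56)))
  if (!is.null(overrides)) scen <- modifyList(scen, overrides)
  structure(scen, class = "genotype_scenario")
}

#' @export
print.genotype_scenario <- function(x, ...) {
  cat("Genotype scenario:", paste(names(x), collapse = ", "), "\n")
  for (g in names(x))
    cat(sprintf("  %-4s X_f ~ %.3g um, wing AR %.3g (n = %d)\n", g,
                x[[g]]$relax$X_f$mean, x[[g]]$wing$mean, x[[g]]$wing$n))
  invisible(x)
}

#' Read / write a scenario as YAML or JSON
#'
#' @param scenario a [genotype_scenario()].
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return Reader returns a `genotype_scenario`; writer returns `path`
#'   invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "genotype_scenario"))
  obj <- unclass(scenario)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "genotype_scenario")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection sampling failed", call. = FALSE)
}

#' Draw recoil parameters for a genotype
#'
#' Samples (X_f, X_s, tau_f, tau_s) from the scenario's truncated-normal
#' distributions for the given genotype. A pure function of
#' (scenario, genotype, seed).
#'
#' @param scenario a [genotype_scenario()].
#' @param genotype one of the scenario's genotype names.
#' @param seed RNG seed (required).
#' @return A [relaxation_params()] object.
#' @export
sample_relaxation_params <- function(scenario, genotype = "wt", seed) {
  stopifnot(inherits(scenario, "genotype_scenario"))
  if (!genotype %in% names(scenario))
    stop("unknown genotype: ", genotype, call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rx <- scenario[[genotype]]$relax
  with_seed(seed, {
    draws <- lapply(rx, function(d) rtruncnorm1(d$mean, d$sd, d$lo, d$hi))
    relaxation_params(X_f = draws$X_f, X_s = draws$X_s,
                      tau_f = draws$tau_f, tau_s = draws$tau_s)
  })
}

#' Generate a noisy displacement trace from known recoil parameters
#'
#' Evaluates the closed-form recoil at frame times offset by the ablation
#' gap (`delta_t`) and adds zero-mean Gaussian noise. The first sample sits
#' at model time `delta_t`, like the first observed frame after a real cut.
#'
#' @param params a [relaxation_params()] (ground truth).
#' @param frame_interval s between frames; default 0.09.
#' @param duration observed duration (s); default 60 (about 3 slow
#'   timescales).
#' @param noise_sd Gaussian noise sd (um); default 0.1.
#' @param delta_t ablation-gap duration (s); default 0.65.
#' @param seed RNG seed (required).
#' @param orientation,genotype,specimen_id optional metadata labels.
#' @return A [displacement_trace()] with attribute `ground_truth = params`.
#' @export
generate_trace <- function(params, frame_interval = 0.09, duration = 60,
                           noise_sd = 0.1, delta_t = 0.65, seed,
                           orientation = NA_character_,
                           genotype = NA_character_,
                           specimen_id = NA_character_) {
  stopifnot(inherits(params, "relaxation_params"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  times <- seq(0, duration - delta_t, by = frame_interval)
  mu <- displacement(times + delta_t, params)
  y <- if (noise_sd > 0) {
    with_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  } else mu
  tr <- displacement_trace(times, y, delta_t = delta_t,
                           orientation = orientation, genotype = genotype,
                           specimen_id = specimen_id)
  attr(tr, "ground_truth") <- params
  tr
}

# Regular hexagon lattice: nx columns x ny rows of hexagons with side s.
hex_lattice <- function(nx, ny, side = 1, region = "blade") {
  w <- sqrt(3) * side   # flat-to-flat width (pointy-top hexagon)
  cells <- list()
  id <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      cx <- (i - 1) * w + ifelse(j %% 2 == 0, w / 2, 0)
      cy <- (j - 1) * 1.5 * side
      id <- id + 1L
      cells[[id]] <- cell_polygon(
        regular_polygon(6, r = side, center = c(cx, cy), phase = pi / 6),
        cell_id = sprintf("c%04d", id), region = region)
    }
  }
  cell_mesh(cells)
}

apply_affine <- function(mesh, mat) {
  cell_mesh(lapply(mesh, function(c)
    cell_polygon(c$vertices %*% t(mat), cell_id = c$cell_id,
                 region = c$region)))
}

# n unit squares laid out in an r x c grid (row-major), cells keep identity.
square_grid <- function(n, n_cols, region = "blade") {
  cells <- vector("list", n)
  for (k in seq_len(n)) {
    i <- (k - 1) %% n_cols          # column
    j <- (k - 1) %/% n_cols         # row
    v <- cbind(c(i, i + 1, i + 1, i), c(j, j, j + 1, j + 1))
    cells[[k]] <- cell_polygon(v, cell_id = sprintf("c%04d", k),
                               region = region)
  }
  cell_mesh(cells)
}

#' Generate a deforming mesh time series
#'
#' Builds a polygonal cell mesh and subjects it to a scripted deformation
#' program:
#' \describe{
#'   \item{`"static"`}{no deformation; all shear contributions are zero.}
#'   \item{`"affine"`}{an area-preserving pure-shear ramp: at step `i` the
#'     hexagonal lattice is mapped by `diag(exp(e_i), exp(-e_i))` with
#'     `e_i = i * strain_step`. No topology change, so the rearrangement
#'     residual is (nearly) zero.}
#'   \item{`"t1"`}{a scripted neighbour-exchange cascade: unit-square cells
#'     rearrange from a single row into a compact block. Individual cell
#'     shapes are identical in every snapshot (mean elongation change is
#'     zero) while the region outline changes shape, so the shear is
#'     carried entirely by rearrangements. Squares are used because they
#'     tile both arrangements exactly.}
#' }
#' Ground truth per-interval region shear and mean-elongation change are
#' attached for oracle tests.
#'
#' @param n_cells number of cells (>= 4); for `"affine"`/`"static"` rounded
#'   to an n x n hexagon lattice.
#' @param program `"static"`, `"affine"` or `"t1"`.
#' @param n_steps number of intervals (snapshots - 1); default 4.
#' @param strain_step Hencky strain increment per step for `"affine"`;
#'   default 0.02.
#' @param seed RNG seed (kept for interface uniformity; the programs are
#'   deterministic).
#' @return A [mesh_series()].
#' @export
generate_mesh_series <- function(n_cells = 100,
                                 program = c("affine", "static", "t1"),
                                 n_steps = 4, strain_step = 0.02, seed = 1) {
  program <- match.arg(program)
  stopifnot(n_cells >= 4, n_steps >= 1)
  times <- seq(0, n_steps)  # hAPF offsets; spacing is immaterial here
  if (program %in% c("static", "affine")) {
    side <- ceiling(sqrt(n_cells))
    base <- hex_lattice(side, side)
    meshes <- lapply(seq_along(times), function(i) {
      e <- if (program == "affine") (i - 1) * strain_step else 0
      apply_affine(base, diag(c(exp(e), exp(-e))))
    })
  } else {
    # T1 cascade: 1 x n row -> most-square block, interpolated in column count
    n_col_seq <- round(seq(n_cells, ceiling(sqrt(n_cells)), length.out = length(times)))
    meshes <- lapply(n_col_seq, function(nc) square_grid(n_cells, max(2, nc)))
  }
  out <- mesh_series(times, meshes)
  attr(out, "ground_truth") <- list(program = program,
                                    strain_step = strain_step)
  out
}

#' Generate a blade-mean elongation time course
#'
#' An asymmetric Gaussian bump sampled every 5 minutes with additive
#' Gaussian noise: elongation rises over `rise_width` hours to
#' `peak_value` at `peak_time` and decays over `decay_width` hours. The
#' true peak time is attached as `ground_truth_peak`.
#'
#' @param scenario a [genotype_scenario()].
#' @param genotype genotype name; default "wt".
#' @param seed RNG seed (required).
#' @return A data.frame with columns `time_hapf`, `elongation`, carrying
#'   attribute `ground_truth_peak`.
#' @export
generate_elongation_timecourse <- function(scenario, genotype = "wt", seed) {
  stopifnot(inherits(scenario, "genotype_scenario"))
  if (!genotype %in% names(scenario))
    stop("unknown genotype: ", genotype, call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  el <- scenario[[genotype]]$elongation
  times <- seq(el$t_start, el$t_end, by = el$dt)
  width <- ifelse(times < el$peak_time, el$rise_width, el$decay_width)
  mu <- el$peak_value * exp(-(times - el$peak_time)^2 / (2 * width^2))
  vals <- if (el$noise_sd > 0) {
    with_seed(seed, mu + rnorm(length(mu), 0, el$noise_sd))
  } else mu
  out <- data.frame(time_hapf = times, elongation = vals)
  attr(out, "ground_truth_peak") <- el$peak_time
  out
}

#' Generate adult-wing aspect-ratio pools
#'
#' Draws Gaussian aspect-ratio pools at the measured pool sizes (wt 53,
#' pk 47, stbm 74, fmi 56) with the scenario's genotype means: pk and stbm
#' slightly rounder (lower ratio) than wt, fmi indistinguishable from wt.
#' With the default calibration the four-group Kruskal-Wallis test on the
#' full pools is significant while three wings per genotype rarely are.
#'
#' @param scenario a [genotype_scenario()].
#' @param seed RNG seed (required).
#' @return A [genotype_samples()] data.frame.
#' @export
generate_wing_pools <- function(scenario, seed) {
  stopifnot(inherits(scenario, "genotype_scenario"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  with_seed(seed, {
    parts <- lapply(names(scenario), function(g) {
      w <- scenario[[g]]$wing
      data.frame(genotype = g,
                 specimen_id = sprintf("%s_%03d", g, seq_len(w$n)),
                 value = rnorm(w$n, w$mean, w$sd))
    })
    do.call(rbind, parts)
  })
}
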