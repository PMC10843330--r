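#' Segmented cell polygon
#'
#' A single cell outline from a segmented epithelium: an ordered list of
#' planar vertices (um). Orientation is normalized to counter-clockwise
#' (positive signed area). Vertices are assumed to describe a simple
#' (non-self-intersecting) polygon, as produced by standard segmentation
#' tools; self-intersection is not checked.
#'
#' @param vertices numeric n x 2 matrix (n >= 3) of (x, y) coordinates, with
#'   x along the proximal-distal axis and y along anterior-posterior.
#' @param cell_id identifier.
#' @param region region label (e.g. "blade", "hinge").
#' @return An object of class `cell_polygon` with attribute `area` (um^2).
#' @export
cell_polygon <- function(vertices, cell_id = NA_character_, region = "blade") {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("`vertices` must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  if (any(!is.finite(vertices))) stop("vertices must be finite", call. = FALSE)
  a <- polygon_area(vertices)
  if (abs(a) < .Machine$double.eps)
    stop("degenerate polygon: zero area", call. = FALSE)
  if (a < 0) { vertices <- vertices[nrow(vertices):1, , drop = FALSE]; a <- -a }
  structure(list(vertices = vertices, cell_id = as.character(cell_id),
                 region = as.character(region)),
            class = "cell_polygon", area = a)
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Second area moments about the origin (integrals of x^2, y^2, xy over the
# polygon), exact shoelace-type formulas.
polygon_second_moments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  Ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  Iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  c(xx = Ixx, yy = Iyy, xy = Ixy, area = sum(cr) / 2)
}

#' Cell elongation nematic tensor
#'
#' Computes the traceless-symmetric cell elongation tensor
#' \deqn{\epsilon_{xx} = \frac{1}{A_c}\int \cos(2\phi)\, dA, \qquad
#'       \epsilon_{xy} = \frac{1}{A_c}\int \sin(2\phi)\, dA,}
#' where \eqn{\phi} is the polar angle of the area element about the cell
#' centroid and \eqn{A_c} the cell area. The integral is evaluated exactly
#' on the centroid triangle fan: for each edge the angular measure reduces
#' to a smooth one-dimensional integral handled by adaptive quadrature
#' (absolute tolerance 1e-7 per edge), so convex and star-shaped cells incur
#' no rasterization error. The tensor is invariant to translation and
#' uniform scaling and rotates by the double angle under rotation of the
#' polygon. The x-component \eqn{\epsilon_{xx}} is the PD component of cell
#' elongation, plotted as Q.
#'
#' @param cell a [cell_polygon()] (or bare vertex matrix).
#' @return An object of class `elongation_tensor`: list with `eps_xx`,
#'   `eps_xy`, `magnitude` \eqn{= \sqrt{\epsilon_{xx}^2+\epsilon_{xy}^2}}
#'   and `angle` \eqn{= \frac{1}{2}\mathrm{atan2}(\epsilon_{xy},
#'   \epsilon_{xx})} (radians).
#' @examples
#' hexagon <- cell_polygon(regular_polygon(6))
#' elongation_tensor(hexagon)  # zero by 6-fold symmetry
#' @export
elongation_tensor <- function(cell) {
  if (!inherits(cell, "cell_polygon")) cell <- cell_polygon(cell)
  v <- cell$vertices
  cen <- polygon_centroid(v)
  v <- sweep(v, 2, cen)
  area <- attr(cell, "area")
  n <- nrow(v)
  I_cos <- I_sin <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    w <- a[1] * b[2] - a[2] * b[1]   # cross(A, B) = cross(A, B - A)
    if (abs(w) < .Machine$double.eps * max(1, sum(a^2), sum(b^2))) next
    d <- b - a
    f_cos <- function(t) {
      px <- a[1] + t * d[1]; py <- a[2] + t * d[2]
      r2 <- px^2 + py^2
      ifelse(r2 > 0, (px^2 - py^2) / r2, 0)
    }
    f_sin <- function(t) {
      px <- a[1] + t * d[1]; py <- a[2] + t * d[2]
      r2 <- px^2 + py^2
      ifelse(r2 > 0, 2 * px * py / r2, 0)
    }
    I_cos <- I_cos + w / 2 * integrate(f_cos, 0, 1, rel.tol = 1e-9,
                                       abs.tol = 1e-7)$value
    I_sin <- I_sin + w / 2 * integrate(f_sin, 0, 1, rel.tol = 1e-9,
                                       abs.tol = 1e-7)$value
  }
  eps_xx <- I_cos / area
  eps_xy <- I_sin / area
  structure(list(eps_xx = eps_xx, eps_xy = eps_xy,
                 magnitude = sqrt(eps_xx^2 + eps_xy^2),
                 angle = 0.5 * atan2(eps_xy, eps_xx)),
            class = "elongation_tensor")
}

#' @export
print.elongation_tensor <- function(x, digits = 4, ...) {
  cat(sprintf("Elongation tensor: eps_xx = %.*g, eps_xy = %.*g (|eps| = %.*g, angle = %.*g rad)\n",
              digits, x$eps_xx, digits, x$eps_xy, digits, x$magnitude,
              digits, x$angle))
  invisible(x)
}

#' Regular polygon vertices
#'
#' Convenience constructor for fixtures: vertices of a regular `n`-gon of
#' circumradius `r` centred at `center`, optionally rotated.
#'
#' @param n number of vertices.
#' @param r circumradius.
#' @param center length-2 centre.
#' @param phase rotation (radians).
#' @return An n x 2 matrix.
#' @export
regular_polygon <- function(n, r = 1, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Collection of cell polygons
#'
#' @param cells list of [cell_polygon()] objects.
#' @return An object of class `cell_mesh` (a list of cells).
#' @export
cell_mesh <- function(cells) {
  stopifnot(is.list(cells), length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "cell_polygon")))
  structure(cells, class = "cell_mesh")
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("Cell mesh: %d cells, regions: %s\n", length(x),
              paste(unique(vapply(x, `[[`, character(1), "region")),
                    collapse = ", ")))
  invisible(x)
}

mesh_region_cells <- function(mesh, region = NULL) {
  stopifnot(inherits(mesh, "cell_mesh"))
  if (is.null(region)) return(mesh)
  keep <- vapply(mesh, function(c) c$region == region, logical(1))
  if (!any(keep)) stop("no cells in region '", region, "'", call. = FALSE)
  mesh[keep]
}

#' Regional mean of the PD elongation component Q
#'
#' The mean of per-cell \eqn{\epsilon_{xx}} over the cells of a region. The
#' default is the unweighted cell mean; `weighted = TRUE` weights cells by
#' area instead (both conventions are found in tissue-scale averaging).
#'
#' @param mesh a [cell_mesh()].
#' @param region region label, or `NULL` for all cells.
#' @param weighted logical; area-weight the mean (default `FALSE`).
#' @return Mean Q (dimensionless).
#' @export
mean_Q <- function(mesh, region = NULL, weighted = FALSE) {
  cells <- mesh_region_cells(mesh, region)
  q <- vapply(cells, function(c) elongation_tensor(c)$eps_xx, numeric(1))
  if (!weighted) return(mean(q))
  w <- vapply(cells, function(c) attr(c, "area"), numeric(1))
  sum(w * q) / sum(w)
}

#' Per-cell elongation table
#'
#' @param mesh a [cell_mesh()].
#' @return A data.frame with columns `cell_id`, `region`, `eps_xx`,
#'   `eps_xy`, `magnitude`, `angle`.
#' @export
elongation_table <- function(mesh) {
  stopifnot(inherits(mesh, "cell_mesh"))
  rows <- lapply(mesh, function(c) {
    e <- elongation_tensor(c)
    data.frame(cell_id = c$cell_id, region = c$region, eps_xx = e$eps_xx,
               eps_xy = e$eps_xy, magnitude = e$magnitude, angle = e$angle)
  })
  do.call(rbind, rows)
}

#' Align a cell-elongation time series to its peak
#'
#' Finds the absolute maximum of blade-mean elongation, least-squares fits a
#' quadratic over a window of `window` samples on each side of it
#' (truncated at the series boundaries), and returns the parabola vertex as
#' the peak time. All times re-expressed relative to this origin are "hours
#' relative to peak cell elongation" (hRPCE). Ties at the maximum are broken
#' to the earliest index and flagged; a vertex falling outside the fitted
#' window falls back to the raw argmax time (flagged); an upward-opening
#' quadratic (no maximum) is an error.
#'
#' @param times sample times (h).
#' @param values blade-mean elongation at `times`.
#' @param window half-width of the fitting window in samples; default 40.
#' @return A list with `peak_time`, `times_rpce` (= `times - peak_time`),
#'   `coefficients` of the quadratic, and `flags`.
#' @export
align_to_peak <- function(times, values, window = 40) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 3)
  flags <- character(0)
  mx <- max(values)
  idx <- which(values == mx)
  if (length(idx) > 1) flags <- c(flags, "tied_maximum")
  i0 <- idx[1]
  lo <- max(1L, i0 - window); hi <- min(length(times), i0 + window)
  if (lo == 1L || hi == length(times)) flags <- c(flags, "truncated_window")
  tw <- times[lo:hi]; vw <- values[lo:hi]
  fit <- lm(vw ~ tw + I(tw^2))
  a <- coef(fit)[[3]]; b <- coef(fit)[[2]]
  if (!is.finite(a) || a >= 0)
    stop("fitted quadratic has no maximum", call. = FALSE)
  peak <- -b / (2 * a)
  if (peak < min(tw) || peak > max(tw)) {
    flags <- c(flags, "vertex_outside_window")
    peak <- times[i0]
  }
  list(peak_time = peak, times_rpce = times - peak,
       coefficients = coef(fit), flags = flags)
}

#' Read / write cell meshes and mesh time series as JSON
#'
#' A mesh is stored as a JSON array of
#' `{cell_id, region, vertices: [[x, y], ...]}`; a time series as an array
#' of `{time_hapf, mesh_file}` referencing mesh files relative to the series
#' file.
#'
#' @param mesh a [cell_mesh()].
#' @param path output path.
#' @return Readers return the object; writers return `path` invisibly.
#' @export
write_cell_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "cell_mesh"))
  obj <- lapply(mesh, function(c)
    list(cell_id = c$cell_id, region = c$region,
         vertices = unname(apply(c$vertices, 1, function(r) as.list(r),
                                 simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_mesh
#' @export
read_cell_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cell_mesh(lapply(obj, function(c) {
    v <- do.call(rbind, lapply(c$vertices, function(p) unlist(p)))
    cell_polygon(v, cell_id = c$cell_id, region = c$region)
  }))
}

#' Mesh time series
#'
#' Ordered snapshots (time in hAPF, [cell_mesh()]) of a deforming tissue.
#'
#' @param times strictly increasing snapshot times (h).
#' @param meshes list of [cell_mesh()] objects, one per time.
#' @return An object of class `mesh_series`.
#' @export
mesh_series <- function(times, meshes) {
  stopifnot(is.numeric(times), length(times) == length(meshes),
            all(diff(times) > 0),
            all(vapply(meshes, inherits, logical(1), "cell_mesh")))
  structure(list(times = as.numeric(times), meshes = meshes),
            class = "mesh_series")
}

#' @export
print.mesh_series <- function(x, ...) {
  cat(sprintf("Mesh time series: %d snapshots, t in [%.3g, %.3g] h\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname write_cell_mesh
#' @param series a [mesh_series()].
#' @export
write_mesh_series <- function(series, path) {
  stopifnot(inherits(series, "mesh_series"))
  dir <- dirname(path)
  base <- sub("\\.json$", "", basename(path))
  entries <- vector("list", length(series$times))
  for (i in seq_along(series$times)) {
    mf <- sprintf("%s_mesh_%03d.json", base, i)
    write_cell_mesh(series$meshes[[i]], file.path(dir, mf))
    entries[[i]] <- list(time_hapf = series$times[i], mesh_file = mf)
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_mesh
#' @export
read_mesh_series <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  times <- vapply(entries, function(e) as.numeric(e$time_hapf), numeric(1))
  meshes <- lapply(entries, function(e)
    read_cell_mesh(file.path(dirname(path), e$mesh_file)))
  mesh_series(times, meshes)
}
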