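#' Post-ablation membrane displacement trace
#'
#' Time-stamped membrane displacement relative to the pre-ablation bond
#' distance. Times are measured in seconds from the first observed
#' post-ablation frame; the unobserved interval while the laser fires (the
#' "dark gap") is carried separately as `delta_t`, so the model time of
#' sample `i` is `times[i] + delta_t`.
#'
#' @param times seconds since the first post-ablation frame; non-negative,
#'   strictly increasing.
#' @param displacements displacement in micrometres, same length as `times`.
#' @param delta_t duration of the unobserved ablation gap (s); default 0.65.
#' @param orientation optional cut orientation label ("PD" or "AP").
#' @param genotype,specimen_id optional identifiers.
#' @return An object of class `displacement_trace`.
#' @seealso [fit_relaxation()], [read_displacement_trace()]
#' @export
displacement_trace <- function(times, displacements, delta_t = 0.65,
                               orientation = NA_character_,
                               genotype = NA_character_,
                               specimen_id = NA_character_) {
  if (!is.numeric(times) || !is.numeric(displacements))
    stop("`times` and `displacements` must be numeric", call. = FALSE)
  if (length(times) != length(displacements))
    stop("`times` and `displacements` must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(displacements)))
    stop("times and displacements must be finite", call. = FALSE)
  if (length(times) > 0 && (times[1] < 0 || any(diff(times) <= 0)))
    stop("`times` must be non-negative and strictly increasing", call. = FALSE)
  stopifnot_scalar(delta_t, "delta_t")
  if (delta_t < 0) stop("`delta_t` must be non-negative", call. = FALSE)
  structure(list(times = as.numeric(times),
                 displacements = as.numeric(displacements),
                 delta_t = delta_t,
                 orientation = as.character(orientation),
                 genotype = as.character(genotype),
                 specimen_id = as.character(specimen_id)),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("Displacement trace: %d points, t in [%.3g, %.3g] s, gap %.3g s\n",
              length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA, x$delta_t))
  meta <- c(orientation = x$orientation, genotype = x$genotype,
            specimen = x$specimen_id)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.displacement_trace <- function(x, ...) {
  data.frame(time_s = x$times, displacement_um = x$displacements)
}

#' @export
length.displacement_trace <- function(x) length(x$times)

#' Read / write displacement traces as annotated CSV
#'
#' The on-disk format is a comma-separated table with header columns
#' `time_s,displacement_um`, preceded by `#`-prefixed metadata lines of the
#' form `# key: value` for `delta_t_s`, `orientation`, `genotype` and
#' `specimen_id`.
#'
#' @param path file path.
#' @return `read_displacement_trace()` returns a [displacement_trace()];
#'   `write_displacement_trace()` returns `path` invisibly.
#' @export
read_displacement_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  tab <- read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                               collapse = "\n"), stringsAsFactors = FALSE)
  if (!all(c("time_s", "displacement_um") %in% names(tab)))
    stop("trace CSV must have columns time_s and displacement_um", call. = FALSE)
  displacement_trace(
    times = as.numeric(tab$time_s),
    displacements = as.numeric(tab$displacement_um),
    delta_t = if (!is.null(meta$delta_t_s)) as.numeric(meta$delta_t_s) else 0.65,
    orientation = if (!is.null(meta$orientation)) meta$orientation else NA_character_,
    genotype = if (!is.null(meta$genotype)) meta$genotype else NA_character_,
    specimen_id = if (!is.null(meta$specimen_id)) meta$specimen_id else NA_character_)
}

#' @rdname read_displacement_trace
#' @param trace a [displacement_trace()] object.
#' @export
write_displacement_trace <- function(trace, path) {
  stopifnot(inherits(trace, "displacement_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# delta_t_s: %.17g", trace$delta_t), con)
  for (nm in c("orientation", "genotype", "specimen_id")) {
    val <- trace[[nm]]
    if (!is.na(val)) writeLines(sprintf("# %s: %s", nm, val), con)
  }
  writeLines("time_s,displacement_um", con)
  writeLines(sprintf("%.10g,%.10g", trace$times, trace$displacements), con)
  invisible(path)
}
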