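#' Genotype-labelled scalar measurements
#'
#' A tidy table of per-specimen scalar measurements (aspect ratio, recoil
#' velocity, ...) grouped by genotype; the common currency of the comparison
#' and resampling functions.
#'
#' @param genotype character vector of group labels.
#' @param value numeric measurements, same length.
#' @param specimen_id optional identifiers (default sequential within group).
#' @return A data.frame with columns `genotype`, `specimen_id`, `value`.
#' @export
genotype_samples <- function(genotype, value, specimen_id = NULL) {
  stopifnot(length(genotype) == length(value), is.numeric(value),
            all(is.finite(value)), length(value) >= 1)
  genotype <- as.character(genotype)
  if (is.null(specimen_id))
    specimen_id <- as.character(stats::ave(seq_along(genotype), genotype,
                                           FUN = seq_along))
  data.frame(genotype = genotype, specimen_id = as.character(specimen_id),
             value = as.numeric(value))
}

#' @rdname genotype_samples
#' @param path CSV path with columns `genotype`, `specimen_id`, `value`.
#' @export
read_genotype_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("genotype", "value") %in% names(tab)))
    stop("CSV must have columns genotype and value", call. = FALSE)
  genotype_samples(tab$genotype, tab$value,
                   if ("specimen_id" %in% names(tab)) tab$specimen_id else NULL)
}

#' @rdname genotype_samples
#' @param samples a `genotype_samples` data.frame.
#' @export
write_genotype_samples <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

split_groups <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("genotype", "value") %in% names(samples)))
  split(samples$value, samples$genotype)
}

#' Normality-gated group comparison
#'
#' Dispatches the appropriate location test: Shapiro-Wilk normality is
#' tested in every group at level `shapiro_alpha`; if all groups pass, two
#' groups are compared by Student's t-test (equal variances) and more by
#' one-way ANOVA; if any group fails, two groups are compared by the
#' Mann-Whitney U-test and more by Kruskal-Wallis. Any non-normal group
#' sends the whole comparison down the nonparametric branch (conservative).
#'
#' @param samples a [genotype_samples()] table with >= 2 groups, each of
#'   size >= 3 (the Shapiro-Wilk minimum).
#' @param alpha significance level for the dispatched test; default 0.05.
#' @param shapiro_alpha level of the normality gate; default 0.05.
#' @return An object of class `group_test`: list with `branch` (one of
#'   `"t"`, `"anova"`, `"wilcoxon"`, `"kruskal"`), `statistic`, `p_value`,
#'   `significant`, `normal` (named logical per group), `alpha`, `n`.
#' @export
dispatch_test <- function(samples, alpha = 0.05, shapiro_alpha = 0.05) {
  groups <- split_groups(samples)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  if (any(n < 3))
    stop("every group needs n >= 3 to test normality", call. = FALSE)
  normal <- vapply(groups, function(v) {
    if (length(unique(v)) == 1) return(FALSE)  # constant: SW undefined
    shapiro.test(v)$p.value > shapiro_alpha
  }, logical(1))
  two <- length(groups) == 2
  if (all(normal)) {
    if (two) {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      branch <- "t"; stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      df <- data.frame(value = unlist(groups, use.names = FALSE),
                       g = factor(rep(names(groups), lengths(groups))))
      sm <- summary(aov(value ~ g, data = df))[[1]]
      branch <- "anova"; stat <- sm[["F value"]][1]; p <- sm[["Pr(>F)"]][1]
    }
  } else {
    if (two) {
      ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
      branch <- "wilcoxon"; stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- kruskal.test(groups)
      branch <- "kruskal"; stat <- unname(ht$statistic); p <- ht$p.value
    }
  }
  structure(list(branch = branch, statistic = stat, p_value = p,
                 significant = p <= alpha, normal = normal, alpha = alpha,
                 n = n),
            class = "group_test")
}

#' @export
print.group_test <- function(x, digits = 4, ...) {
  cat(sprintf("Group comparison (%s branch): statistic = %.*g, p = %.*g%s\n",
              x$branch, digits, x$statistic, digits, x$p_value,
              if (x$significant) " *" else ""))
  cat("  normality gate:",
      paste(sprintf("%s=%s", names(x$normal), ifelse(x$normal, "normal", "non-normal")),
            collapse = ", "), "\n")
  invisible(x)
}

# Tie-corrected Kruskal-Wallis H statistic for a fixed group layout.
kw_statistic <- function(values, group_sizes) {
  n <- length(values)
  r <- rank(values)
  idx <- rep.int(seq_along(group_sizes), group_sizes)
  rs <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / group_sizes) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr <= 0) return(NA_real_)  # all observations tied
  h / tie_corr
}

#' Fraction of significant Kruskal-Wallis tests on resampled subgroups
#'
#' Repeats `n_iter` times: draw `m` values with replacement from every
#' group, run a Kruskal-Wallis test across the resampled groups, and record
#' whether p <= `alpha`. The returned fraction estimates the power to detect
#' the groups' difference from samples of size `m` per group. Degenerate
#' resamples in which every value is tied are counted as non-significant
#' (and reported via the `n_degenerate` attribute). Reproducible given
#' `seed`.
#'
#' For small per-group sizes the chi-squared reference of the Kruskal-Wallis
#' statistic is approximate and discrete; `method = "permutation"` instead
#' compares the observed tie-corrected H to `n_perm` random permutations of
#' the group labels (recommended for m <= 5 when accuracy of individual
#' p-values matters; markedly slower).
#'
#' @param samples a [genotype_samples()] table.
#' @param m resampled size per group (>= 2).
#' @param n_iter number of resampling iterations; default 10000.
#' @param alpha significance level; default 0.05.
#' @param seed RNG seed (required).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm permutations per iteration for `method = "permutation"`.
#' @return Fraction of significant iterations in \[0, 1\], with attribute
#'   `n_degenerate`.
#' @export
subsample_power <- function(samples, m, n_iter = 10000, alpha = 0.05, seed,
                            method = c("chisq", "permutation"), n_perm = 400) {
  method <- match.arg(method)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(m >= 2, n_iter >= 1)
  groups <- split_groups(samples)
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  sizes <- rep.int(m, k)
  df_chisq <- k - 1
  n_tot <- m * k
  with_seed(seed, {
    n_sig <- 0L; n_degen <- 0L
    for (it in seq_len(n_iter)) {
      vals <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), m, replace = TRUE)]), use.names = FALSE)
      h <- kw_statistic(vals, sizes)
      if (is.na(h)) { n_degen <- n_degen + 1L; next }
      p <- if (method == "chisq") {
        pchisq(h, df_chisq, lower.tail = FALSE)
      } else {
        hp <- replicate(n_perm, kw_statistic(vals[sample.int(n_tot)], sizes))
        (1 + sum(hp >= h, na.rm = TRUE)) / (n_perm + 1)
      }
      if (p <= alpha) n_sig <- n_sig + 1L
    }
    structure(n_sig / n_iter, n_degenerate = n_degen)
  })
}

#' Power curve over subsample sizes
#'
#' Runs [subsample_power()] for each size in `sizes` (default the ladder
#' 3-10, 20, 40) and collects the results.
#'
#' @inheritParams subsample_power
#' @param sizes per-group subsample sizes.
#' @return An object of classes `power_curve`/`data.frame` with columns `m`,
#'   `fraction_significant`, `n_iter`, `alpha`, `seed`.
#' @export
power_curve <- function(samples, sizes = c(3:10, 20, 40), n_iter = 10000,
                        alpha = 0.05, seed, method = c("chisq", "permutation"),
                        n_perm = 400) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(length(sizes) >= 1)
  method <- match.arg(method)
  frac <- vapply(seq_along(sizes), function(i)
    as.numeric(subsample_power(samples, sizes[i], n_iter = n_iter,
                               alpha = alpha, seed = seed + i - 1L,
                               method = method, n_perm = n_perm)),
    numeric(1))
  structure(data.frame(m = sizes, fraction_significant = frac,
                       n_iter = n_iter, alpha = alpha, seed = seed),
            class = c("power_curve", "data.frame"))
}

#' @export
plot.power_curve <- function(x, ...) {
  plot(x$m, x$fraction_significant, type = "b", pch = 16, log = "x",
       xlab = "subsample size m (per group)",
       ylab = "fraction of significant resamples", ylim = c(0, 1), ...)
  invisible(x)
}

#' Major-to-minor axis ratio of a shape
#'
#' The aspect ratio of the area-normalized second-moment ellipse:
#' \eqn{\sqrt{\lambda_{max}/\lambda_{min}}} of the central second-moment
#' tensor. Accepts either a polygon outline (numeric n x 2 vertex matrix,
#' exact moments) or a binary mask (logical matrix, pixel moments). Always
#' >= 1; invariant to rotation, translation and uniform scaling.
#'
#' @param outline numeric n x 2 polygon vertex matrix, or logical mask
#'   matrix.
#' @return Dimensionless ratio >= 1.
#' @export
aspect_ratio <- function(outline) {
  stopifnot(is.matrix(outline))
  is_mask <- is.logical(outline) || ncol(outline) != 2
  if (is_mask) {
    idx <- which(outline != 0, arr.ind = TRUE)
    if (nrow(idx) < 2) stop("degenerate mask", call. = FALSE)
    x <- idx[, 1]; y <- idx[, 2]
    mxx <- var(x) * (length(x) - 1) / length(x)
    myy <- var(y) * (length(y) - 1) / length(y)
    mxy <- stats::cov(x, y) * (length(x) - 1) / length(x)
  } else {
    v <- as.matrix(outline)
    stopifnot(ncol(v) == 2, nrow(v) >= 3)
    a <- polygon_area(v)
    if (abs(a) < .Machine$double.eps) stop("degenerate outline", call. = FALSE)
    if (a < 0) v <- v[nrow(v):1, , drop = FALSE]
    m <- polygon_second_moments(v)
    cen <- polygon_centroid(v)
    A <- m[["area"]]
    mxx <- m[["xx"]] / A - cen[1]^2
    myy <- m[["yy"]] / A - cen[2]^2
    mxy <- m[["xy"]] / A - cen[1] * cen[2]
  }
  tr <- mxx + myy
  disc <- sqrt(max((mxx - myy)^2 / 4 + mxy^2, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 0) stop("degenerate outline: zero minor axis", call. = FALSE)
  sqrt(l1 / l2)
}

#' Write a power curve as CSV or JSON
#'
#' @param curve a [power_curve()].
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_power_curve <- function(curve, path) {
  stopifnot(inherits(curve, "power_curve"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(curve), path, digits = NA)
  } else {
    write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
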