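# Curve processing: ingestion of force-extension (F-E) retraction curves,
# segmentation of the adhesion peak and detachment, normalization at a
# reference force, and ensemble overlay dispersion.

#' Construct a force-extension curve
#'
#' @param extension_nm,force_pN Numeric vectors of equal length (>= 10
#'   samples), in acquisition order.
#' @param id Curve identifier.
#' @param environment Environment label (e.g. `"DI"`, `"pH3"`).
#' @param metadata Named list of further metadata (e.g. pulling velocity).
#' @return An object of class `fe_curve` with a `samples` data frame.
#' @export
fe_curve <- function(extension_nm, force_pN, id = "curve1",
                     environment = NA_character_, metadata = list()) {
  if (length(extension_nm) != length(force_pN)) {
    stop("extension and force must have equal length")
  }
  if (length(extension_nm) < 10) stop("a curve needs at least 10 samples")
  if (!all(is.finite(extension_nm)) || !all(is.finite(force_pN))) {
    stop("all samples must be finite")
  }
  if (!(max(extension_nm) > 0)) stop("maximum extension must be positive")
  structure(
    list(samples = data.frame(extension_nm = as.numeric(extension_nm),
                              force_pN = as.numeric(force_pN)),
         id = as.character(id),
         environment = as.character(environment),
         metadata = metadata),
    class = "fe_curve"
  )
}

#' @export
print.fe_curve <- function(x, ...) {
  cat(sprintf("F-E curve '%s' (%s): %d samples, extension up to %.1f nm, force up to %.0f pN\n",
              x$id, x$environment, nrow(x$samples),
              max(x$samples$extension_nm), max(x$samples$force_pN)))
  invisible(x)
}

#' Read force-extension curves from a TSV file
#'
#' The dialect is: optional `#key: value` metadata lines, then a header line
#' `extension_nm<TAB>force_pN`, then data rows; multiple curves in one file
#' are separated by blank lines.  The `#id` and `#environment` keys populate
#' the curve fields; other keys land in `metadata`.
#'
#' @param path File path.
#' @return A list of [fe_curve()] objects.
#' @seealso [write_curves()] for the writer emitting the same dialect.
#' @export
load_curves <- function(path, format = c("tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  blocks <- split(seq_along(lines), cumsum(!nzchar(trimws(lines))))
  curves <- list()
  for (block in blocks) {
    idx <- block[nzchar(trimws(lines[block]))]
    if (length(idx) == 0) next
    meta <- list()
    header_seen <- FALSE
    ext <- numeric(0); frc <- numeric(0)
    for (i in idx) {
      ln <- trimws(lines[i])
      if (startsWith(ln, "#")) {
        kv <- sub("^#\\s*", "", ln)
        key <- trimws(sub(":.*$", "", kv))
        val <- trimws(sub("^[^:]*:", "", kv))
        meta[[key]] <- val
      } else if (!header_seen) {
        cols <- strsplit(ln, "\t")[[1]]
        if (!identical(cols, c("extension_nm", "force_pN"))) {
          stop(sprintf("line %d: expected header 'extension_nm\\tforce_pN', got '%s'",
                       i, ln))
        }
        header_seen <- TRUE
      } else {
        fields <- strsplit(ln, "\t")[[1]]
        vals <- suppressWarnings(as.numeric(fields))
        if (length(vals) != 2 || anyNA(vals)) {
          stop(sprintf("line %d: malformed data row '%s'", i, ln))
        }
        ext <- c(ext, vals[1]); frc <- c(frc, vals[2])
      }
    }
    if (!header_seen) stop("curve block missing 'extension_nm\\tforce_pN' header")
    id <- if (!is.null(meta$id)) meta$id else sprintf("curve%d", length(curves) + 1)
    env <- if (!is.null(meta$environment)) meta$environment else NA_character_
    meta$id <- NULL; meta$environment <- NULL
    curves[[length(curves) + 1]] <-
      fe_curve(ext, frc, id = id, environment = env, metadata = meta)
  }
  if (length(curves) == 0) stop(sprintf("no curves found in %s", path))
  curves
}

#' Write force-extension curves in the TSV dialect read by [load_curves()]
#'
#' @param curves A list of [fe_curve()] objects (or a single curve).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "fe_curve")) curves <- list(curves)
  con <- file(path, "w")
  on.exit(close(con))
  first <- TRUE
  for (cv in curves) {
    if (!first) writeLines("", con)
    first <- FALSE
    writeLines(sprintf("#id: %s", cv$id), con)
    if (!is.na(cv$environment)) {
      writeLines(sprintf("#environment: %s", cv$environment), con)
    }
    for (key in names(cv$metadata)) {
      writeLines(sprintf("#%s: %s", key, as.character(cv$metadata[[key]])), con)
    }
    writeLines("extension_nm\tforce_pN", con)
    writeLines(sprintf("%.17g\t%.17g",
                       cv$samples$extension_nm, cv$samples$force_pN), con)
  }
  invisible(path)
}

# Robust per-sample noise scale from successive differences (trend-immune).
noise_scale <- function(force) {
  if (length(force) < 3) return(0)
  stats::mad(diff(force)) / sqrt(2)
}

#' Segment a retraction curve into adhesion, stretch and detachment
#'
#' The adhesion region is the initial force peak caused by nonspecific
#' tip-surface attraction: the leading samples up to the point where force
#' first returns to within noise of the baseline after the initial peak.
#' Detachment is the first abrupt force drop after the global force maximum
#' that loses at least `drop_fraction` of the running maximum within a
#' 3-sample window; a curve without such a drop is flagged unruptured and its
#' stretch region runs to the last sample.
#'
#' @param curve An [fe_curve()].
#' @param baseline_window Number of lowest (smoothed) force samples used to
#'   estimate the baseline force.
#' @param drop_fraction Fraction of the running force maximum that must be
#'   lost within 3 samples to call detachment.
#' @return A list of class `curve_segmentation` with `adhesion_end_index`
#'   (0 when no adhesion peak is found), `stretch_start_index`,
#'   `detachment_index` (`NA` when unruptured), `baseline_force` and
#'   `unruptured`.
#' @export
segment_curve <- function(curve, baseline_window = 50, drop_fraction = 0.8) {
  f <- curve$samples$force_pN
  n <- length(f)
  k <- min(5, if (n %% 2 == 0) n - 1 else n)
  fs <- if (k >= 3) stats::runmed(f, k) else f
  sigma <- noise_scale(f)
  baseline <- stats::median(utils::head(sort(fs), min(baseline_window, n)))
  thr <- baseline + max(3 * sigma, 2)

  imax <- which.max(fs)

  # adhesion: first excursion above threshold that returns to baseline
  # before the global maximum; its end is the local force minimum after the
  # return (exact at zero noise, where the spike kink is the minimum)
  adhesion_end <- 0L
  above <- which(fs > thr)
  i1 <- if (length(above)) above[1] else NA_integer_
  if (!is.na(i1) && i1 < imax) {
    ret <- which(fs[seq(i1, imax)] <= thr)
    if (length(ret)) {
      icross <- i1 + ret[1] - 1L
      rise <- which(fs[seq(icross, imax)] > thr)
      iend <- if (length(rise)) icross + rise[1] - 2L else imax
      # local minimum just after the return to baseline; the short window
      # keeps the estimate from drifting through flat noise-floor regions
      iend <- min(iend, icross + 10L)
      adhesion_end <- icross + which.min(fs[seq(icross, iend)]) - 1L
    }
  }
  stretch_start <- adhesion_end + 1L

  # detachment: abrupt loss of >= drop_fraction of the running maximum
  # within 3 samples, after the global maximum; guarded against flat traces
  detach <- NA_integer_
  peak_guard <- max(10, 5 * sigma)
  if (imax < n) {
    runmax <- cummax(f)
    for (i in seq(imax + 1L, n)) {
      if (runmax[i - 1L] <= peak_guard) next
      wstart <- max(imax, i - 3L)
      if (max(f[wstart:(i - 1L)]) - f[i] >= drop_fraction * runmax[i - 1L]) {
        detach <- i
        break
      }
    }
  }

  structure(
    list(adhesion_end_index = adhesion_end,
         stretch_start_index = stretch_start,
         detachment_index = detach,
         baseline_force = baseline,
         unruptured = is.na(detach)),
    class = "curve_segmentation"
  )
}

# Stretch-region samples as a data frame, monotonized for interpolation:
# sorted by force with duplicate forces averaged.
stretch_samples <- function(curve, segmentation) {
  last <- if (is.na(segmentation$detachment_index)) nrow(curve$samples) else
    segmentation$detachment_index - 1L
  s <- curve$samples[seq(segmentation$stretch_start_index, last), ]
  s <- s[order(s$force_pN), ]
  agg <- stats::aggregate(extension_nm ~ force_pN, data = s, FUN = mean)
  agg[order(agg$force_pN), ]
}

#' Interpolated extension at a target force
#'
#' Linear interpolation of extension versus force over the monotonized
#' stretch region (samples sorted by force, duplicate forces averaged).
#'
#' @param curve An [fe_curve()].
#' @param segmentation Its [segment_curve()] result.
#' @param target_force Force in pN at which to evaluate the extension.
#' @return Extension in nm.
#' @export
extension_at_force <- function(curve, segmentation, target_force) {
  s <- stretch_samples(curve, segmentation)
  if (target_force > max(s$force_pN)) {
    stop(sprintf("curve '%s' does not reach %g pN (max %g pN)",
                 curve$id, target_force, max(s$force_pN)))
  }
  if (target_force < min(s$force_pN)) {
    stop(sprintf("curve '%s': %g pN is below the stretch region", curve$id,
                 target_force))
  }
  stats::approx(s$force_pN, s$extension_nm, xout = target_force,
                ties = "ordered")$y
}

#' Normalize a curve by its extension at a reference force
#'
#' Divides every stretch-region extension by the interpolated extension at
#' `reference_force` (1500 pN by default, where polysaccharide elasticity is
#' backbone-dominated and environment-independent), excluding the adhesion
#' region and any samples outside (0, reference_force].  Normalized curves
#' from chains of different contour length overlay onto a single master
#' curve.
#'
#' @param curve An [fe_curve()] or an already-normalized curve (identity).
#' @param segmentation [segment_curve()] result; computed when `NULL`.
#' @param reference_force Reference force, pN.
#' @return An object of class `normalized_curve` with samples
#'   `(z, force_pN)` and fields `reference_force`, `id`, `environment`.
#' @export
normalize_curve <- function(curve, segmentation = NULL,
                            reference_force = 1500) {
  if (inherits(curve, "normalized_curve")) {
    if (curve$reference_force != reference_force) {
      stop("re-normalization at a different reference force is not supported")
    }
    return(curve)
  }
  if (is.null(segmentation)) segmentation <- segment_curve(curve)
  x_ref <- extension_at_force(curve, segmentation, reference_force)
  s <- stretch_samples(curve, segmentation)
  keep <- s$force_pN > 0 & s$force_pN <= reference_force
  s <- s[keep, ]
  z <- s$extension_nm / x_ref
  force <- s$force_pN
  if (max(force) < reference_force) {
    # anchor the curve at the reference point it was normalized to
    z <- c(z, 1)
    force <- c(force, reference_force)
  }
  structure(
    list(samples = data.frame(z = z, force_pN = force),
         reference_force = reference_force,
         id = curve$id,
         environment = curve$environment),
    class = "normalized_curve"
  )
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("Normalized F-E curve '%s' (%s): %d samples, reference %g pN\n",
              x$id, x$environment, nrow(x$samples), x$reference_force))
  invisible(x)
}

# Interpolate a normalized curve's z at given forces.
normalized_z_at <- function(ncurve, forces) {
  s <- ncurve$samples[order(ncurve$samples$force_pN), ]
  if (min(forces) < min(s$force_pN) || max(forces) > max(s$force_pN)) {
    stop(sprintf("force grid outside the range of curve '%s' (%.3g-%.3g pN)",
                 ncurve$id, min(s$force_pN), max(s$force_pN)))
  }
  stats::approx(s$force_pN, s$z, xout = forces, ties = mean)$y
}

#' Overlay dispersion of a normalized-curve ensemble
#'
#' Quantifies how well normalized curves overlap: the root-mean-square over a
#' force grid of the per-force standard deviation of normalized extension
#' across curves.  Near-zero dispersion indicates a shared single-chain
#' elasticity.
#'
#' @param ncurves List of [normalize_curve()] results (>= 2).
#' @param force_grid Forces (pN) at which to compare; must lie inside every
#'   curve's force range.
#' @return Dispersion statistic, dimensionless.
#' @export
overlay_dispersion <- function(ncurves, force_grid = seq(50, 1500, by = 50)) {
  if (length(ncurves) < 2) stop("need at least 2 curves")
  zmat <- vapply(ncurves, normalized_z_at, numeric(length(force_grid)),
                 forces = force_grid)
  sds <- apply(zmat, 1, stats::sd)
  sqrt(mean(sds^2))
}
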