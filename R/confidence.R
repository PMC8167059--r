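#' Noise region specification
#'
#' Describes the cubes of background ("noise boxes") used to estimate the
#' null intensity distribution: a set of cube centers (0-based voxel index
#' triples) and a common odd edge length in voxels. Cubes must lie entirely
#' inside the grid and must not overlap each other.
#'
#' @param cube_centers integer matrix, one row per cube, columns i,j,k
#'   (0-based voxel indices of the cube centers).
#' @param edge_voxels odd integer >= 3, cube edge length in voxels.
#' @param map optional [density_map()]; when given, containment inside the
#'   grid is validated.
#' @return an object of class `noise_regions`.
#' @export
noise_regions <- function(cube_centers, edge_voxels, map = NULL) {
  cube_centers <- matrix(as.integer(round(cube_centers)), ncol = 3L,
                         dimnames = list(NULL, c("i", "j", "k")))
  edge_voxels <- as.integer(edge_voxels)
  if (edge_voxels < 3L || edge_voxels %% 2L == 0L)
    stop("edge_voxels must be an odd integer >= 3", call. = FALSE)
  h <- (edge_voxels - 1L) %/% 2L
  if (!is.null(map)) {
    lo <- sweep(cube_centers, 2L, h, "-")
    hi <- sweep(cube_centers, 2L, h, "+")
    if (any(lo < 0L) || any(hi > rep(map$dims - 1L, each = nrow(cube_centers))))
      stop("noise cube extends outside the map grid", call. = FALSE)
  }
  if (nrow(cube_centers) > 1L) {
    for (a in seq_len(nrow(cube_centers) - 1L)) {
      for (b in (a + 1L):nrow(cube_centers)) {
        if (all(abs(cube_centers[a, ] - cube_centers[b, ]) < edge_voxels))
          stop("noise cubes overlap", call. = FALSE)
      }
    }
  }
  structure(list(cube_centers = cube_centers, edge_voxels = edge_voxels),
            class = "noise_regions")
}

#' @export
print.noise_regions <- function(x, ...) {
  cat(sprintf("<noise_regions> %d cube(s), edge %d voxels (%d voxels pooled)\n",
              nrow(x$cube_centers), x$edge_voxels,
              nrow(x$cube_centers) * x$edge_voxels^3L))
  invisible(x)
}

# 0-based index triples of all voxels in one cube
.cube_indices <- function(center, edge) {
  h <- (edge - 1L) %/% 2L
  as.matrix(expand.grid(i = (center[1L] - h):(center[1L] + h),
                        j = (center[2L] - h):(center[2L] + h),
                        k = (center[3L] - h):(center[3L] + h)))
}

.cube_values <- function(map, regions) {
  lapply(seq_len(nrow(regions$cube_centers)), function(r) {
    map_value_at(map, .cube_indices(regions$cube_centers[r, ],
                                    regions$edge_voxels))
  })
}

#' Default placement of background noise cubes
#'
#' Places four noise cubes on the central x and y axes of the box, flush
#' against the box faces (one voxel in), outside a central guard sphere of
#' radius `guard_fraction * min(map_cell(map))` that is assumed to contain
#' the particle. Positions and edge can be overridden by constructing a
#' [noise_regions()] directly.
#'
#' @param map a [density_map()].
#' @param edge_voxels odd cube edge in voxels; default is the largest odd
#'   integer `<= 0.125 * min(dims)`, with a floor of 5.
#' @param guard_fraction fraction (0-0.5) of the smallest box extent used as
#'   the guard-sphere radius; default 0.35.
#' @return a [noise_regions()] with four cubes.
#' @export
default_noise_regions <- function(map, edge_voxels = NULL, guard_fraction = 0.35) {
  stopifnot(inherits(map, "density_map"))
  if (guard_fraction < 0 || guard_fraction > 0.5)
    stop("guard_fraction must be in [0, 0.5]", call. = FALSE)
  if (is.null(edge_voxels)) {
    edge_voxels <- floor(min(map$dims) * 0.125)
    if (edge_voxels %% 2L == 0L) edge_voxels <- edge_voxels - 1L
    edge_voxels <- max(edge_voxels, 5L)
  }
  edge_voxels <- as.integer(edge_voxels)
  if (edge_voxels < 3L || edge_voxels %% 2L == 0L)
    stop("edge_voxels must be an odd integer >= 3", call. = FALSE)
  h <- (edge_voxels - 1L) %/% 2L
  ctr <- (map$dims - 1L) / 2                    # box center, 0-based voxels
  r_guard <- guard_fraction * min(map_cell(map))
  centers <- rbind(
    c(1L + h,                ctr[2L], ctr[3L]),   # -x face
    c(map$dims[1L] - 2L - h, ctr[2L], ctr[3L]),   # +x face
    c(ctr[1L], 1L + h,                ctr[3L]),   # -y face
    c(ctr[1L], map$dims[2L] - 2L - h, ctr[3L]))   # +y face
  centers <- round(centers)
  # nearest point of each cube to the box center must be outside the guard
  # sphere (distances in Angstrom, voxel centers)
  for (r in seq_len(nrow(centers))) {
    lo <- centers[r, ] - h
    hi <- centers[r, ] + h
    nearest <- pmin(pmax(ctr, lo), hi)
    d <- sqrt(sum(((nearest - ctr) * map$voxel_size)^2))
    if (any(lo < 0) || any(hi > map$dims - 1L) || d < r_guard)
      stop(sprintf(paste0(
        "box too small to host %d-voxel noise cubes outside the guard ",
        "sphere (radius %.1f A); reduce edge_voxels or guard_fraction"),
        edge_voxels, r_guard), call. = FALSE)
  }
  noise_regions(centers, edge_voxels, map = map)
}

#' Diagnose noise cubes for signal contamination
#'
#' Computes per-cube mean/sd and flags any cube whose mean exceeds the mean
#' of the pooled *other* cubes by more than `k` standard errors
#' (`k * pooled_sd / sqrt(n_cube)`), suggesting that the cube overlaps
#' molecular signal. Cubes with zero spread are flagged as degenerate.
#' Purely diagnostic; nothing is modified.
#'
#' @param map a [density_map()].
#' @param regions a [noise_regions()].
#' @param k flag threshold in standard errors (default 5).
#' @return data.frame with one row per cube: `cube`, `n`, `mean`, `sd`,
#'   `flagged`, `reason` ("" | "signal?" | "degenerate").
#' @export
check_noise_regions <- function(map, regions, k = 5) {
  vals <- .cube_values(map, regions)
  n_cube <- regions$edge_voxels^3
  means <- vapply(vals, mean, numeric(1))
  sds <- vapply(vals, stats::sd, numeric(1))
  flagged <- logical(length(vals))
  reason <- character(length(vals))
  for (r in seq_along(vals)) {
    if (sds[r] == 0) {
      flagged[r] <- TRUE
      reason[r] <- "degenerate"
      next
    }
    others <- unlist(vals[-r])
    if (length(others) == 0L) next
    if (means[r] - mean(others) > k * stats::sd(others) / sqrt(n_cube)) {
      flagged[r] <- TRUE
      reason[r] <- "signal?"
    }
  }
  data.frame(cube = seq_along(vals), n = n_cube, mean = means, sd = sds,
             flagged = flagged, reason = reason)
}

#' Estimate the background noise distribution
#'
#' Pools all voxels of the noise cubes and fits a single Gaussian: mean and
#' sample standard deviation. A zero standard deviation (e.g. a masked,
#' solvent-flattened map) is a hard error since no null distribution can be
#' estimated from it.
#'
#' @param map a [density_map()].
#' @param regions a [noise_regions()].
#' @return an object of class `noise_estimate` with fields `mean`, `sd`,
#'   `n_voxels`, `regions`.
#' @export
estimate_noise <- function(map, regions) {
  v <- unlist(.cube_values(map, regions))
  mu <- mean(v)
  sigma <- stats::sd(v)
  if (!is.finite(sigma) || sigma <= 0)
    stop(paste0("degenerate background (sd = 0) in the noise cubes; masked ",
                "maps with the solvent background removed are unsuitable ",
                "for confidence-map calculation - use an unmasked map"),
         call. = FALSE)
  structure(list(mean = mu, sd = sigma, n_voxels = length(v),
                 regions = regions),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> mean %.5g, sd %.5g (from %d voxels in %d cubes)\n",
              x$mean, x$sd, x$n_voxels, nrow(x$regions$cube_centers)))
  invisible(x)
}

#' Voxel-wise right-tailed p-values against the background
#'
#' For each voxel value v, p = 1 - Phi((v - mu)/sigma): the probability that
#' pure background reaches v or more. Signal is assumed to be positive
#' density (sharpened maps), hence the one-sided test.
#'
#' @param map a [density_map()].
#' @param noise a `noise_estimate`.
#' @return numeric 3D array of p-values, same dims as the map.
#' @export
voxel_p_values <- function(map, noise) {
  stopifnot(inherits(noise, "noise_estimate"), noise$sd > 0)
  p <- stats::pnorm(map$values, mean = noise$mean, sd = noise$sd,
                    lower.tail = FALSE)
  # keep p in (0,1): pnorm underflows to 0 for extreme z
  array(pmax(p, .Machine$double.xmin), dim = map$dims)
}

#' Step-up false discovery rate adjustment (BY / BH)
#'
#' Adjusts p-values with the Benjamini-Hochberg step-up procedure, or the
#' Benjamini-Yekutieli variant which multiplies by the harmonic correction
#' c(m) = sum_{i=1}^{m} 1/i and is valid under arbitrary dependence between
#' tests (the default for voxel grids, whose values are strongly
#' correlated). Adjusted values are made monotone by a running minimum from
#' the largest p downward, clipped at 1, and returned in input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method "by" (Benjamini-Yekutieli, default) or "bh"
#'   (Benjamini-Hochberg).
#' @return numeric vector of adjusted q-values in (0, 1], input order.
#' @export
fdr_adjust <- function(p, method = c("by", "bh")) {
  method <- match.arg(tolower(method[1L]), c("by", "bh"))
  if (length(p) == 0L) stop("empty p-value input", call. = FALSE)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  cm <- if (method == "by") sum(1 / seq_len(m)) else 1
  o <- order(p, decreasing = TRUE)           # largest p first
  ro <- order(o)
  i <- m:1L                                  # ranks of the sorted sequence
  q <- cummin(cm * m / i * p[o])
  pmin(1, q)[ro]
}

#' Confidence map object
#'
#' A `confidence_map` is a [density_map()] whose voxel values are
#' 1 - q, with q the FDR-adjusted p-value of the voxel against the
#' background noise model: 0 means indistinguishable from background, 1
#' means clear molecular signal. Carries the FDR method label and the noise
#' estimate as provenance.
#'
#' @param map a [density_map()] on whose grid the confidences live.
#' @param values 3D array of confidences in [0, 1].
#' @param fdr_method "by" or "bh".
#' @param noise the `noise_estimate` used.
#' @return an object of class `c("confidence_map", "density_map")`.
#' @keywords internal
new_confidence_map <- function(map, values, fdr_method, noise) {
  out <- density_map(values, voxel_size = map$voxel_size, origin = map$origin)
  out$fdr_method <- fdr_method
  out$noise <- noise
  class(out) <- c("confidence_map", "density_map")
  out
}

#' Compute an FDR confidence map from a density map
#'
#' Estimates the background noise from the given (or default) noise cubes,
#' converts every voxel to a right-tailed Gaussian p-value, adjusts the
#' p-values for multiplicity across all voxels, and returns the confidence
#' map c = 1 - q. At the conventional threshold c >= 0.99 at most 1% of the
#' voxels passing are expected to be background (1% FDR).
#'
#' @param map a [density_map()].
#' @param regions a [noise_regions()]; default [default_noise_regions()].
#' @param method FDR adjustment, "by" (default) or "bh".
#' @return a `confidence_map`.
#' @export
confidence_map <- function(map, regions = NULL, method = c("by", "bh")) {
  method <- match.arg(tolower(method[1L]), c("by", "bh"))
  stopifnot(inherits(map, "density_map"))
  if (is.null(regions)) regions <- default_noise_regions(map)
  noise <- estimate_noise(map, regions)
  p <- voxel_p_values(map, noise)
  q <- fdr_adjust(as.vector(p), method = method)
  conf <- array(1 - q, dim = map$dims)
  new_confidence_map(map, conf, method, noise)
}

#' Write the provenance sidecar of a confidence map
#'
#' Emits a small JSON file recording the FDR method, the noise estimate and
#' the cube specification, sufficient to reproduce the calculation.
#'
#' @param cmap a `confidence_map`.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_confidence_sidecar <- function(cmap, path) {
  stopifnot(inherits(cmap, "confidence_map"))
  info <- list(
    type = "fdr_confidence_map",
    fdr_method = toupper(cmap$fdr_method),
    noise_mean = cmap$noise$mean,
    noise_sd = cmap$noise$sd,
    noise_n_voxels = cmap$noise$n_voxels,
    cube_edge_voxels = cmap$noise$regions$edge_voxels,
    cube_centers = apply(cmap$noise$regions$cube_centers, 1L, identity,
                         simplify = FALSE)
  )
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
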