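#' Density map objects
#'
#' A `density_map` holds a 3D voxel grid together with its physical
#' geometry: per-axis voxel spacing in Angstrom and the world coordinate of
#' the *center* of voxel (0,0,0). Values are stored as doubles in
#' crystallographic X,Y,Z axis order regardless of the storage order of the
#' file they came from.
#'
#' @param values numeric 3D array of map values (finite).
#' @param voxel_size numeric length-1 or length-3, Angstrom per voxel along
#'   X, Y, Z. Must be strictly positive and finite.
#' @param origin numeric length-3, world coordinate (Angstrom) of the center
#'   of voxel (0,0,0).
#' @return An object of class `density_map` with fields `values`,
#'   `voxel_size`, `origin`, `dims`.
#' @export
density_map <- function(values, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 numeric", call. = FALSE)
  if (!all(is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("all voxel_size components must be strictly positive and finite",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("map contains non-finite values (NaN/Inf)", call. = FALSE)
  storage.mode(values) <- "double"
  structure(
    list(values = values, voxel_size = voxel_size, origin = origin,
         dims = dim(values)),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<%s> %d x %d x %d voxels, voxel size %s A, origin (%s) A\n",
              class(x)[1L], x$dims[1L], x$dims[2L], x$dims[3L],
              paste(format(x$voxel_size, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  v <- range(x$values)
  cat(sprintf("  value range [%.4g, %.4g]\n", v[1L], v[2L]))
  invisible(x)
}

#' Physical cell edge lengths of a map
#'
#' @param map a `density_map`.
#' @return numeric length-3, `dims * voxel_size` in Angstrom.
#' @export
map_cell <- function(map) {
  map$dims * map$voxel_size
}

# ---------------------------------------------------------------------------
# MRC2014 I/O. Header is 1024 bytes of 4-byte words; data follow the header
# (plus any extended header). Only modes 0 (int8), 1 (int16) and 2 (float32)
# are accepted; mode 2 is written.

.mrc_read_header <- function(con, endian) {
  h <- list()
  ints1 <- readBin(con, "integer", n = 10L, size = 4L, endian = endian)
  h$nc <- ints1[1L]; h$nr <- ints1[2L]; h$ns <- ints1[3L]
  h$mode <- ints1[4L]
  h$nstart <- ints1[5:7]
  h$m <- ints1[8:10]
  h$cella <- readBin(con, "double", n = 3L, size = 4L, endian = endian)
  h$cellb <- readBin(con, "double", n = 3L, size = 4L, endian = endian)
  h$mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = endian)
  h$dstats <- readBin(con, "double", n = 3L, size = 4L, endian = endian)
  h$ispg <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  h$nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  invisible(readBin(con, "raw", n = 100L))            # extra words 26-49
  h$origin <- readBin(con, "double", n = 3L, size = 4L, endian = endian)
  h$map <- rawToChar(readBin(con, "raw", n = 4L))
  h$machst <- readBin(con, "raw", n = 4L)
  h$rms <- readBin(con, "double", n = 1L, size = 4L, endian = endian)
  h$nlabl <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  invisible(readBin(con, "raw", n = 800L))            # labels
  h
}

.mrc_header_plausible <- function(h) {
  is.finite(h$mode) && h$mode %in% c(0L, 1L, 2L, 6L) &&
    all(is.finite(c(h$nc, h$nr, h$ns))) &&
    all(c(h$nc, h$nr, h$ns) >= 1L) && all(c(h$nc, h$nr, h$ns) <= 100000L)
}

#' Read an MRC2014 density map
#'
#' Reads a volume in MRC2014 format, reorders the grid so that axes are
#' crystallographic X,Y,Z (honouring `mapc`/`mapr`/`maps`), and resolves the
#' map origin: the MRC `origin` record is used when any component is nonzero,
#' otherwise `nstart * voxel_size` (the common single-particle convention).
#' Voxel size is `cella / (mx, my, mz)` per axis.
#'
#' @param path path to an MRC2014 file.
#' @return a [density_map()].
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  h <- .mrc_read_header(con, endian)
  if (!.mrc_header_plausible(h)) {
    close(con); on.exit()
    con <- file(path, "rb")
    on.exit(close(con))
    endian <- "big"
    h <- .mrc_read_header(con, endian)
  }
  if (!.mrc_header_plausible(h))
    stop("malformed MRC header in ", path, call. = FALSE)
  if (!h$mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", h$mode, " (only 0, 1, 2 supported)",
         call. = FALSE)
  if (!identical(sort(h$mapcrs), 1:3))
    stop("malformed MRC header: mapc/mapr/maps must be a permutation of 1:3",
         call. = FALSE)
  if (h$nsymbt > 0L) invisible(readBin(con, "raw", n = h$nsymbt))
  n <- h$nc * h$nr * h$ns
  vals <- switch(as.character(h$mode),
    "0" = as.double(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.double(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                            endian = endian)),
    "2" = readBin(con, "double", n = n, size = 4L, endian = endian))
  if (length(vals) != n)
    stop("truncated MRC data block in ", path, call. = FALSE)
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("MRC data contain non-finite values (NaN/Inf)", call. = FALSE)
  arr <- array(vals, dim = c(h$nc, h$nr, h$ns))

  # storage axis i holds crystallographic axis h$mapcrs[i]; permute to X,Y,Z
  perm <- match(1:3, h$mapcrs)
  arr <- aperm(arr, perm)
  nstart_xyz <- h$nstart[perm]

  m <- h$m
  m[m <= 0L] <- dim(arr)[m <= 0L]
  voxel_size <- h$cella / m
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    voxel_size <- rep(1, 3)
    warning("MRC header has no usable cell dimensions; assuming 1 A voxels",
            call. = FALSE)
  }
  if (diff(range(voxel_size)) > 1e-4 * max(voxel_size))
    message("note: anisotropic (non-cubic) voxels: ",
            paste(format(voxel_size, digits = 5), collapse = " x "), " A")
  origin <- if (any(h$origin != 0)) h$origin else nstart_xyz * voxel_size
  density_map(arr, voxel_size = voxel_size, origin = origin)
}

#' Write a density map as MRC2014
#'
#' Writes mode-2 (32-bit float) data in X,Y,Z storage order
#' (`mapc,mapr,maps = 1,2,3`), with cell dimensions `dims * voxel_size`, the
#' origin record set from the map origin, and `nstart = 0`.
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- map$dims
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                       # nc, nr, ns
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nstart
  wi(d)                       # mx, my, mz
  wf(d * map$voxel_size)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(1:3)                     # mapc, mapr, maps
  v <- map$values
  wf(c(min(v), max(v), mean(v)))
  wi(c(0L, 0L))               # ispg, nsymbt
  extra <- integer(25L)       # header words 25-49
  extra[3L] <- 20140L         # word 27: nversion (MRC2014)
  wi(extra)
  wf(map$origin)              # origin record (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst little-endian
  wf(stats::sd(v))            # rms
  wi(1L)                      # nlabl
  lab <- sprintf("%-80s", "fdrmap density map")
  writeBin(charToRaw(lab), con)
  writeBin(raw(800L - 80L), con)
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Geometry. Voxel indices are 0-based throughout the public geometry API
# (the MRC convention); the origin is the world coordinate of the CENTER of
# voxel (0,0,0) and distances are measured to voxel centers.

#' Convert world coordinates (Angstrom) to fractional voxel indices
#'
#' @param map a [density_map()].
#' @param coord numeric length-3 world coordinate, or an n x 3 matrix.
#' @return fractional 0-based voxel indices, same shape as `coord`.
#' @export
world_to_voxel <- function(map, coord) {
  if (is.matrix(coord))
    sweep(sweep(coord, 2L, map$origin, "-"), 2L, map$voxel_size, "/")
  else
    (coord - map$origin) / map$voxel_size
}

#' Convert voxel indices to world coordinates (Angstrom)
#'
#' Inverse of [world_to_voxel()].
#' @param map a [density_map()].
#' @param idx 0-based voxel index triple (possibly fractional), or n x 3 matrix.
#' @return world coordinates in Angstrom.
#' @export
voxel_to_world <- function(map, idx) {
  if (is.matrix(idx))
    sweep(sweep(idx, 2L, map$voxel_size, "*"), 2L, map$origin, "+")
  else
    idx * map$voxel_size + map$origin
}

#' Grid voxels within a radius of a world coordinate
#'
#' Returns the (0-based) integer indices of all voxels whose centers lie
#' within `radius` Angstrom (true Euclidean distance, honouring anisotropic
#' voxels) of `coord` and inside the grid. May be empty.
#'
#' @param map a [density_map()].
#' @param coord numeric length-3 world coordinate (Angstrom).
#' @param radius search radius in Angstrom (> 0).
#' @return integer matrix with columns i, j, k (0-based), zero or more rows.
#' @export
voxels_within_radius <- function(map, coord, radius) {
  stopifnot(length(coord) == 3L, radius > 0)
  fr <- world_to_voxel(map, coord)
  lo <- pmax(ceiling(fr - radius / map$voxel_size), 0)
  hi <- pmin(floor(fr + radius / map$voxel_size), map$dims - 1L)
  if (any(lo > hi))
    return(matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "k"))))
  g <- as.matrix(expand.grid(i = as.integer(lo[1L]:hi[1L]),
                             j = as.integer(lo[2L]:hi[2L]),
                             k = as.integer(lo[3L]:hi[3L])))
  centers <- voxel_to_world(map, g)
  d2 <- (centers[, 1L] - coord[1L])^2 + (centers[, 2L] - coord[2L])^2 +
    (centers[, 3L] - coord[3L])^2
  g[d2 <= radius^2, , drop = FALSE]
}

#' Look up map values at 0-based voxel indices
#'
#' @param map a [density_map()].
#' @param idx integer 0-based index triple or n x 3 matrix of triples.
#' @return numeric vector of map values.
#' @export
map_value_at <- function(map, idx) {
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 3L)
  map$values[idx + 1L]
}
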