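# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route so they share no code path with the package.

# O(m^2) step-up FDR adjustment: q_(i) = min_{j >= i} min(1, c(m)*m/j * p_(j))
fdr_adjust_brute <- function(p, method = "by") {
  m <- length(p)
  cm <- if (method == "by") sum(1 / seq_len(m)) else 1
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, cm * m / j * ps[j])
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive scan of every voxel center for the within-radius query
voxels_within_radius_brute <- function(map, coord, radius) {
  g <- as.matrix(expand.grid(i = 0:(map$dims[1L] - 1L),
                             j = 0:(map$dims[2L] - 1L),
                             k = 0:(map$dims[3L] - 1L)))
  centers <- voxel_to_world(map, g)
  d <- sqrt(rowSums(sweep(centers, 2L, coord, "-")^2))
  g[d <= radius, , drop = FALSE]
}

# minimal reader for the UCSF Chimera defattr grammar
parse_defattr <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("^attribute: [a-z][A-Za-z0-9_]*$", lines[1L]),
            identical(lines[2L], "match mode: 1-to-1"),
            identical(lines[3L], "recipient: residues"))
  body <- lines[-(1:3)]
  m <- regmatches(body,
    regexec("^\t:([0-9]+)([A-Za-z]?)\\.([A-Za-z0-9]+)\t(-?[0-9]*\\.?[0-9]+)$",
            body))
  stopifnot(all(lengths(m) == 5L))
  data.frame(resno = as.integer(vapply(m, `[`, "", 2L)),
             insert = vapply(m, `[`, "", 3L),
             chain = vapply(m, `[`, "", 4L),
             value = as.numeric(vapply(m, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

# write an MRC2014 file whose storage axes are a chosen permutation of the
# crystallographic axes (reference transpose done with aperm here)
write_mrc_permuted <- function(map, path, mapcrs) {
  stopifnot(identical(sort(mapcrs), 1:3))
  stor <- aperm(map$values, mapcrs)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dim(stor))                       # nc, nr, ns
  wi(2L)                              # mode
  wi(c(0L, 0L, 0L))                   # nstart
  wi(map$dims)                        # mx, my, mz (crystallographic)
  wf(map$dims * map$voxel_size)       # cella
  wf(c(90, 90, 90))
  wi(mapcrs)                          # mapc, mapr, maps
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(0L, 0L))
  extra <- integer(25L); extra[3L] <- 20140L
  wi(extra)
  wf(map$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(stats::sd(map$values))
  wi(0L)
  writeBin(raw(800L), con)
  writeBin(as.numeric(stor), con, size = 4L, endian = "little")
  invisible(path)
}

# a pure-noise map with a reproducible seed
pure_noise_map <- function(dims, seed, sd = 1) {
  vals <- withr::with_seed(seed, stats::rnorm(prod(dims), 0, sd))
  density_map(array(vals, dim = dims))
}

# round doubles through float32, as a file round-trip does
as_float32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4L)
  r <- rawConnectionValue(con)
  close(con)
  readBin(r, "double", n = length(x), size = 4L)
}
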