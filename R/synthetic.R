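# Synthetic test scenes: toy backbone models rendered as sums of Gaussian
# atoms in a box, plus i.i.d. Gaussian background noise and a ground-truth
# signal mask. These stand in for experimental maps so every pipeline stage
# is testable without downloads; they make no attempt at resolution realism
# (no form factors, CTF or B-factor falloff).

.unit <- function(v) v / sqrt(sum(v^2))

.perp_unit <- function(d) {
  e <- if (abs(d[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  .unit(e - sum(e * d) * d)
}

#' Build an extended toy backbone chain
#'
#' A poly-alanine-like straight chain: consecutive CA atoms 3.8 Angstrom
#' apart along `direction`; N and C placed 1.46 / 1.52 Angstrom before and
#' after each CA along the chain axis; the carbonyl O offset 1.23 Angstrom
#' perpendicular to the axis.
#'
#' @param n_residues number of residues (>= 1).
#' @param start world coordinate of the first CA (Angstrom).
#' @param direction chain direction (normalised internally).
#' @param chain chain identifier (default "A").
#' @return an `atomic_model` with atoms N, CA, C, O per residue.
#' @export
make_toy_chain <- function(n_residues, start = c(0, 0, 0),
                           direction = c(1, 1, 1), chain = "A") {
  stopifnot(n_residues >= 1L)
  d <- .unit(as.numeric(direction))
  perp <- .perp_unit(d)
  rows <- lapply(seq_len(n_residues), function(i) {
    ca <- start + (i - 1) * 3.8 * d
    pos <- rbind(ca - 1.46 * d,      # N
                 ca,                 # CA
                 ca + 1.52 * d,      # C
                 ca + 1.52 * d + 1.23 * perp)   # O
    data.frame(chain = chain, resno = i, insert = "", resid = "ALA",
               elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
               stringsAsFactors = FALSE)
  })
  as_atomic_model(do.call(rbind, rows), format = "pdb")
}

#' Render a model as a Gaussian-atom density map
#'
#' Every non-hydrogen atom contributes `amplitude * exp(-d^2 / (2 sigma^2))`
#' to the grid (evaluated out to 5 sigma; the truncated mass is < 0.01%).
#' The ground-truth signal mask marks voxels within `mask_radius`
#' (default 2.5 sigma) of any atom.
#'
#' @param model an `atomic_model`.
#' @param voxel_size Angstrom per voxel (cubic).
#' @param box_dims voxel counts, length 3.
#' @param sigma_atom Gaussian width per atom, Angstrom.
#' @param amplitude peak value of a single atom.
#' @param origin world coordinate of voxel (0,0,0) center.
#' @param mask_radius truth-mask radius in Angstrom (default 2.5 sigma).
#' @param min_margin_voxels required margin between any atom and every box
#'   face, in voxels (default 8, so that default noise cubes stay
#'   signal-free); violating it is an error.
#' @return list with `map` (a [density_map()]) and `mask` (logical array).
#' @export
render_map <- function(model, voxel_size = 1, box_dims = c(64, 64, 64),
                       sigma_atom = 1, amplitude = 1, origin = c(0, 0, 0),
                       mask_radius = 2.5 * sigma_atom,
                       min_margin_voxels = 8) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms[!model$atoms$is_h, , drop = FALSE]
  dims <- as.integer(box_dims)
  vals <- array(0, dim = dims)
  mask <- array(FALSE, dim = dims)
  shell <- density_map(vals, voxel_size = voxel_size, origin = origin)

  fr <- world_to_voxel(shell, as.matrix(a[, c("x", "y", "z")]))
  margin <- min_margin_voxels
  if (any(fr < margin) || any(fr > rep(dims - 1 - margin, each = nrow(fr))))
    stop(sprintf("model does not fit inside the box with a %d-voxel margin",
                 as.integer(margin)), call. = FALSE)

  reach <- max(ceiling(5 * sigma_atom / voxel_size),
               ceiling(mask_radius / voxel_size))
  for (i in seq_len(nrow(a))) {
    pos <- c(a$x[i], a$y[i], a$z[i])
    ctr <- round(fr[i, ])
    lo <- pmax(ctr - reach, 0)
    hi <- pmin(ctr + reach, dims - 1L)
    ii <- lo[1L]:hi[1L]; jj <- lo[2L]:hi[2L]; kk <- lo[3L]:hi[3L]
    dx2 <- (ii * voxel_size + origin[1L] - pos[1L])^2
    dy2 <- (jj * voxel_size + origin[2L] - pos[2L])^2
    dz2 <- (kk * voxel_size + origin[3L] - pos[3L])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    g <- amplitude * exp(-d2 / (2 * sigma_atom^2))
    g[d2 > (5 * sigma_atom)^2] <- 0
    vals[ii + 1L, jj + 1L, kk + 1L] <- vals[ii + 1L, jj + 1L, kk + 1L] + g
    mask[ii + 1L, jj + 1L, kk + 1L] <- mask[ii + 1L, jj + 1L, kk + 1L] |
      (d2 <= mask_radius^2)
  }
  list(map = density_map(vals, voxel_size = voxel_size, origin = origin),
       mask = mask)
}

#' Add i.i.d. Gaussian background noise to a map
#'
#' Reproducible given `seed`; the global random state is left untouched.
#'
#' @param map a [density_map()].
#' @param noise_sd noise standard deviation (>= 0; 0 is the identity).
#' @param seed integer seed.
#' @return a new [density_map()].
#' @export
add_noise <- function(map, noise_sd, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(map)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(map$values), 0, noise_sd))
  density_map(map$values + array(noise, dim = map$dims),
              voxel_size = map$voxel_size, origin = map$origin)
}

#' Rigidly displace selected residues of a model
#'
#' Translates all atoms of the listed residues by `offset`; every other atom
#' is untouched. Used to fabricate mistraced residues whose backbone sits in
#' background rather than signal.
#'
#' @param model an `atomic_model`.
#' @param residues integer vector of residue numbers to displace.
#' @param offset numeric length-3 translation in Angstrom.
#' @param chain restrict to this chain (default: all chains).
#' @return a modified copy of `model`.
#' @export
displace_residues <- function(model, residues, offset, chain = NULL) {
  stopifnot(inherits(model, "atomic_model"), length(offset) == 3L)
  sel <- model$atoms$resno %in% residues
  if (!is.null(chain)) sel <- sel & model$atoms$chain %in% chain
  out <- model
  out$atoms$x[sel] <- out$atoms$x[sel] + offset[1L]
  out$atoms$y[sel] <- out$atoms$y[sel] + offset[2L]
  out$atoms$z[sel] <- out$atoms$z[sel] + offset[3L]
  out
}

#' Generate a complete synthetic validation scene
#'
#' Builds a toy chain through the box center along the (1,1,1) diagonal
#' (keeping it away from the default noise-cube positions on the face
#' midpoints), renders the clean Gaussian-atom map and ground-truth mask
#' from the *true* chain, adds background noise, and optionally displaces
#' some residues of the returned model to fabricate mistraces. The density
#' always comes from the true (undisplaced) chain, so displaced residues of
#' the model sit in pure background.
#'
#' @param n_residues chain length (default 10).
#' @param box_dims voxel counts (default 64^3).
#' @param voxel_size Angstrom per voxel (default 1).
#' @param sigma_atom atom Gaussian width in Angstrom (default 1).
#' @param amplitude peak atom amplitude (default 5).
#' @param noise_sd background noise sd (default 1); SNR = amplitude/noise_sd.
#' @param seed integer seed for the noise.
#' @param displace residue numbers to displace in the returned model
#'   (default none).
#' @param displace_offset translation applied to displaced residues
#'   (default `c(0, 0, -8)` Angstrom, which moves a residue about 6.5
#'   Angstrom off the chain axis, well clear of the 2.5 sigma truth mask).
#' @return an object of class `synthetic_scene`: list with `model` (the
#'   model to validate, including any mistraces), `true_model`, `clean_map`,
#'   `noisy_map`, `truth_mask` and `params`.
#' @export
synthetic_scene <- function(n_residues = 10, box_dims = c(64, 64, 64),
                            voxel_size = 1, sigma_atom = 1, amplitude = 5,
                            noise_sd = 1, seed = 1, displace = integer(0),
                            displace_offset = c(0, 0, -8)) {
  d <- .unit(c(1, 1, 1))
  center <- (box_dims - 1) / 2 * voxel_size
  start <- center - d * (n_residues - 1) * 3.8 / 2
  true_model <- make_toy_chain(n_residues, start = start, direction = d)
  rendered <- render_map(true_model, voxel_size = voxel_size,
                         box_dims = box_dims, sigma_atom = sigma_atom,
                         amplitude = amplitude)
  noisy <- add_noise(rendered$map, noise_sd, seed)
  model <- if (length(displace))
    displace_residues(true_model, displace, displace_offset) else true_model
  structure(list(
    model = model, true_model = true_model,
    clean_map = rendered$map, noisy_map = noisy,
    truth_mask = rendered$mask,
    params = list(n_residues = n_residues, box_dims = box_dims,
                  voxel_size = voxel_size, sigma_atom = sigma_atom,
                  amplitude = amplitude, noise_sd = noise_sd,
                  snr = amplitude / noise_sd, seed = seed,
                  displaced = displace, displace_offset = displace_offset)
  ), class = "synthetic_scene")
}
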