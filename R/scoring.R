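#' Scoring configuration
#'
#' @param association_radius radius in Angstrom within which voxels are
#'   associated with an atom (default 1.0).
#' @param mode which atoms are scored per residue: "backbone" (default) or
#'   "ca_only"; see [select_score_atoms()].
#' @param aggregation how the map values of the associated voxels are
#'   reduced to one value per atom: "max" (default), "mean" or "nearest".
#' @return an object of class `scoring_config`.
#' @export
scoring_config <- function(association_radius = 1.0,
                           mode = c("backbone", "ca_only"),
                           aggregation = c("max", "mean", "nearest")) {
  if (!is.numeric(association_radius) || association_radius <= 0)
    stop("association_radius must be > 0", call. = FALSE)
  structure(list(association_radius = association_radius,
                 mode = match.arg(mode),
                 aggregation = match.arg(aggregation)),
            class = "scoring_config")
}

# is a world coordinate inside the grid (its nearest voxel exists)?
.inside_grid <- function(map, coord) {
  fr <- world_to_voxel(map, coord)
  all(fr >= -0.5) && all(fr < map$dims - 0.5)
}

.nearest_voxel_value <- function(map, coord) {
  idx <- pmin(pmax(round(world_to_voxel(map, coord)), 0), map$dims - 1L)
  map_value_at(map, idx)
}

#' Map value associated with one atomic position
#'
#' Gathers the voxels whose centers lie within `association_radius` of the
#' position and aggregates their map values (max by default). If no voxel
#' center falls within the radius but the position is still inside the grid,
#' the nearest voxel's value is used. Positions outside the grid score 0 and
#' are flagged.
#'
#' @param map a [density_map()] (normally a `confidence_map`).
#' @param position numeric length-3 world coordinate (Angstrom).
#' @param config a [scoring_config()].
#' @return numeric value with attribute `out_of_grid` (logical).
#' @export
atom_score <- function(map, position, config = scoring_config()) {
  if (!.inside_grid(map, position))
    return(structure(0, out_of_grid = TRUE))
  idx <- voxels_within_radius(map, position, config$association_radius)
  val <- if (nrow(idx) == 0L) {
    .nearest_voxel_value(map, position)
  } else {
    v <- map_value_at(map, idx)
    switch(config$aggregation,
      max = max(v),
      mean = mean(v),
      nearest = {
        centers <- voxel_to_world(map, idx)
        d2 <- rowSums(sweep(centers, 2L, position, "-")^2)
        v[which.min(d2)]
      })
  }
  structure(val, out_of_grid = FALSE)
}

#' Score one residue against a confidence map
#'
#' The residue score is the arithmetic mean of the per-atom values of the
#' scoring atoms ([select_score_atoms()]): for proteins in backbone mode the
#' mean over N, CA and C. An empty selection yields an NA score with
#' `n_atoms_scored = 0`.
#'
#' @param map a [density_map()] or `confidence_map`.
#' @param residue_atoms data.frame of one residue's atoms.
#' @param config a [scoring_config()].
#' @return a one-row data.frame: chain, resno, insert, resid, category,
#'   n_atoms_scored, score, out_of_grid, plus an `atom_scores` list-column
#'   (named numeric vector, one entry per scored atom).
#' @export
residue_score <- function(map, residue_atoms, config = scoring_config()) {
  sel <- select_score_atoms(residue_atoms, mode = config$mode)
  n <- nrow(sel)
  oog <- FALSE
  atom_scores <- stats::setNames(numeric(0), character(0))
  if (n > 0L) {
    vals <- numeric(n)
    for (i in seq_len(n)) {
      s <- atom_score(map, c(sel$x[i], sel$y[i], sel$z[i]), config)
      vals[i] <- as.numeric(s)
      oog <- oog || isTRUE(attr(s, "out_of_grid"))
    }
    atom_scores <- stats::setNames(vals, sel$elety)
  }
  out <- data.frame(
    chain = residue_atoms$chain[1L],
    resno = residue_atoms$resno[1L],
    insert = residue_atoms$insert[1L],
    resid = residue_atoms$resid[1L],
    category = .residue_category(residue_atoms$resid, residue_atoms$elety),
    n_atoms_scored = n,
    score = if (n > 0L) mean(atom_scores) else NA_real_,
    z_score = NA_real_,
    out_of_grid = oog,
    stringsAsFactors = FALSE
  )
  out$res_key <- .res_key(out$chain, out$resno, out$insert)
  out$atom_scores <- list(atom_scores)
  out
}

#' Score every residue of a model
#'
#' Applies [residue_score()] to each residue in file order and fills in
#' per-chain z-scores ([chain_zscores()]). If the map values fall outside
#' [0,1] (i.e. it is not a confidence map), a warning is emitted and the raw
#' values are reported unclamped.
#'
#' @param map a [density_map()] or `confidence_map`.
#' @param model an `atomic_model`.
#' @param config a [scoring_config()].
#' @return a `residue_scores` data.frame, one row per residue in file order.
#' @export
score_model <- function(map, model, config = scoring_config()) {
  stopifnot(inherits(model, "atomic_model"))
  rng <- range(map$values)
  if (rng[1L] < 0 || rng[2L] > 1)
    warning(paste0("map values outside [0,1]: not a confidence map; ",
                   "raw values are reported unclamped"), call. = FALSE)
  a <- model$atoms
  keys <- unique(a$res_key)
  rows <- lapply(keys, function(k) {
    residue_score(map, a[a$res_key == k, , drop = FALSE], config)
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  scores <- chain_zscores(scores)
  class(scores) <- c("residue_scores", class(scores))
  scores
}

#' Per-chain z-scores of residue scores
#'
#' z = (score - chain mean) / chain sd, computed per chain over the scored
#' residues; waters are excluded from the chain statistics (they are not
#' part of a polymer distribution) and keep an NA z-score. A degenerate
#' chain sd of 0 yields z = 0. The score distribution is usually far from
#' normal (most residues score 1.0), so z-scores are advisory; prefer the
#' absolute score for mistrace detection.
#'
#' @param scores a `residue_scores` data.frame.
#' @return the same data.frame with `z_score` filled in.
#' @export
chain_zscores <- function(scores) {
  scores$z_score <- NA_real_
  for (ch in unique(scores$chain)) {
    sel <- scores$chain == ch & !is.na(scores$score) &
      scores$category != "water"
    if (sum(sel) < 2L) next
    mu <- mean(scores$score[sel])
    sdev <- stats::sd(scores$score[sel])
    scores$z_score[sel] <- if (sdev == 0) 0 else (scores$score[sel] - mu) / sdev
  }
  scores
}

#' Write residue scores as CSV
#'
#' One row per residue: chain, residue_number, insertion_code, residue_name,
#' category, n_atoms_scored, score (3 decimals), z_score (3 decimals).
#'
#' @param scores a `residue_scores` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  out <- data.frame(
    chain = scores$chain,
    residue_number = scores$resno,
    insertion_code = scores$insert,
    residue_name = scores$resid,
    category = scores$category,
    n_atoms_scored = scores$n_atoms_scored,
    score = ifelse(is.na(scores$score), "", sprintf("%.3f", scores$score)),
    z_score = ifelse(is.na(scores$z_score), "", sprintf("%.3f", scores$z_score)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a UCSF Chimera residue attribute file
#'
#' Emits the `defattr` format: header lines `attribute: <name>`,
#' `match mode: 1-to-1`, `recipient: residues`, then one tab-indented line
#' per scored residue, `:<resnum><icode>.<chain>\t<score>` (3 decimals).
#' Residues without a score are omitted.
#'
#' @param scores a `residue_scores` data.frame.
#' @param attribute_name attribute identifier (must start with a lowercase
#'   letter; letters/digits/underscore only).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chimera_attributes <- function(scores, attribute_name = "fdr_score",
                                     path) {
  if (!grepl("^[a-z][A-Za-z0-9_]*$", attribute_name))
    stop("invalid attribute name: ", attribute_name, call. = FALSE)
  keep <- !is.na(scores$score)
  lines <- c(
    sprintf("attribute: %s", attribute_name),
    "match mode: 1-to-1",
    "recipient: residues",
    sprintf("\t:%d%s.%s\t%.3f",
            scores$resno[keep], scores$insert[keep], scores$chain[keep],
            scores$score[keep])
  )
  writeLines(lines, path)
  invisible(path)
}
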