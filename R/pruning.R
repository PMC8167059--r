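#' Pruning configuration
#'
#' @param threshold residues with a score strictly below this are removed
#'   (default 0.9, the conventional cutoff below which a residue usually
#'   reflects a clear backbone mistrace).
#' @param flank number of neighbouring residues removed on each side of a
#'   removed polymer residue (default 1), so the region can be rebuilt
#'   cleanly in the next model-building round.
#' @return an object of class `prune_config`.
#' @export
prune_config <- function(threshold = 0.9, flank = 1L) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]",
                                           call. = FALSE)
  flank <- as.integer(flank)
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  structure(list(threshold = threshold, flank = flank),
            class = "prune_config")
}

#' Prune low-confidence residues from a model
#'
#' Removes every residue scoring below the threshold. For polymer residues
#' (protein/nucleic) the `flank` preceding and following residues of the
#' same chain are removed as well, where "preceding/following" means
#' adjacency in the chain's residue list in file order (robust to insertion
#' codes and numbering gaps; windows are truncated at chain ends and never
#' cross chains). Ligands and waters below the threshold are removed without
#' flanking. Unscored residues are retained.
#'
#' @param model an `atomic_model`.
#' @param scores a `residue_scores` data.frame from [score_model()].
#' @param config a [prune_config()].
#' @return list with `model` (the pruned `atomic_model`) and `report` (a
#'   data.frame of removed residues: chain, resno, insert, resid, score,
#'   reason = "below_threshold" or "flanking"; attribute `retained` holds
#'   per-chain retained counts).
#' @export
prune_model <- function(model, scores, config = prune_config()) {
  stopifnot(inherits(model, "atomic_model"))
  rt <- residue_table(model)
  sc <- stats::setNames(scores$score, scores$res_key)
  res_score <- sc[rt$res_key]
  below <- !is.na(res_score) & res_score < config$threshold

  reason <- rep(NA_character_, nrow(rt))
  reason[below] <- "below_threshold"

  polymer <- rt$category %in% c("protein", "nucleic")
  for (ch in unique(rt$chain)) {
    pos <- which(rt$chain == ch & polymer)      # chain's polymer residues,
    if (length(pos) == 0L) next                 # file order
    hit <- which(below[pos])
    if (length(hit) == 0L || config$flank == 0L) next
    for (h in hit) {
      win <- setdiff(max(1L, h - config$flank):min(length(pos), h + config$flank), h)
      fl <- pos[win]
      reason[fl][is.na(reason[fl])] <- "flanking"
    }
  }

  removed <- !is.na(reason)
  report <- data.frame(
    chain = rt$chain[removed], resno = rt$resno[removed],
    insert = rt$insert[removed], resid = rt$resid[removed],
    score = unname(res_score[removed]), reason = reason[removed],
    res_key = rt$res_key[removed],
    stringsAsFactors = FALSE
  )
  keep_keys <- rt$res_key[!removed]
  pruned <- model
  pruned$atoms <- model$atoms[model$atoms$res_key %in% keep_keys, ,
                              drop = FALSE]
  rownames(pruned$atoms) <- NULL
  retained <- table(rt$chain[!removed])
  attr(report, "retained") <- as.list(retained)
  list(model = pruned, report = report)
}

#' Write the list of pruned residues
#'
#' Plain text, one removed residue per line: chain, residue number with
#' insertion code, residue name, score, reason.
#'
#' @param report the `report` component of [prune_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prune_report <- function(report, path) {
  lines <- sprintf("%s %d%s %s %s %s",
                   report$chain, report$resno, report$insert, report$resid,
                   ifelse(is.na(report$score), "NA",
                          sprintf("%.3f", report$score)),
                   report$reason)
  writeLines(lines, path)
  invisible(path)
}
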