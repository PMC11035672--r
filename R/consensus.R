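## Pixel-wise majority-vote fusion of several annotations of one
## (frame, structure) task.
##
## MV is an absolute vote-count threshold (4-of-5 for bowel, 2-of-5 for
## abdominal wall in the shipped defaults), not a fraction; under a count
## threshold there are no ties. mv = 1 gives the union of the annotations,
## mv = n the intersection.

#' Per-pixel vote counts over a set of masks
#'
#' @param masks non-empty list of `binary_mask`s / logical matrices with
#'   identical dimensions.
#' @return an integer matrix; each pixel holds the number of masks that
#'   contain it.
#' @export
vote_counts <- function(masks) {
  if (length(masks) == 0) stop("vote_counts: empty annotation set", call. = FALSE)
  mats <- lapply(masks, as_mask_matrix)
  for (m in mats[-1]) check_same_dim(mats[[1]], m)
  counts <- Reduce(`+`, lapply(mats, function(m) m * 1L))
  storage.mode(counts) <- "integer"
  counts
}

#' Majority-vote consensus mask
#'
#' The consensus foreground is the set of pixels annotated by at least `mv`
#' of the contributing masks.
#'
#' @param masks non-empty list of masks with identical dimensions.
#' @param mv absolute vote threshold, `1 <= mv <= length(masks)`.
#' @return a `binary_mask`.
#' @export
majority_vote <- function(masks, mv) {
  if (length(masks) == 0) stop("majority_vote: empty annotation set", call. = FALSE)
  if (!is.numeric(mv) || length(mv) != 1 || mv < 1 || mv > length(masks))
    stop("majority_vote: mv must satisfy 1 <= mv <= ", length(masks),
         " (got ", mv, ")", call. = FALSE)
  binary_mask(vote_counts(masks) >= mv)
}

#' Build the consensus record for one task
#'
#' Applies the structure-specific (n, MV) parameters from the campaign
#' configuration to the qualified annotations of one (frame, structure)
#' task. If fewer than `n_min` qualified annotations are available the task
#' is returned as *pending* rather than raising, so batch runs continue.
#'
#' When more than `n_min` qualified annotations exist, all contribute; with
#' `scale_mv = TRUE` (default) the vote threshold is rescaled as
#' `ceiling(mv / n_min * n_used)` to preserve the voting fraction, otherwise
#' the absolute threshold is kept.
#'
#' @param annotations list of `annotation` records, all for one
#'   (frame, structure).
#' @param config a [campaign_config()].
#' @param qualified_ids character vector of annotator ids qualified at
#'   submission time; defaults to all contributors.
#' @return a `consensus_record`: `frame_id`, `structure`, `status`
#'   (`"complete"` or `"pending"`), `mask`, `contributor_ids`,
#'   `vote_threshold_used`, `n_used`.
#' @export
build_consensus <- function(annotations, config, qualified_ids = NULL) {
  if (length(annotations) == 0) stop("build_consensus: no annotations", call. = FALSE)
  frame_id <- unique(vapply(annotations, `[[`, character(1), "frame_id"))
  struct <- unique(vapply(annotations, `[[`, character(1), "structure"))
  if (length(frame_id) != 1 || length(struct) != 1)
    stop("build_consensus: annotations span multiple (frame, structure) tasks",
         call. = FALSE)
  params <- structure_params(config, struct)
  ids <- vapply(annotations, `[[`, character(1), "annotator_id")
  if (anyDuplicated(ids))
    stop("build_consensus: duplicate annotator for task (", frame_id, ", ",
         struct, ")", call. = FALSE)
  keep <- if (is.null(qualified_ids)) rep(TRUE, length(ids)) else ids %in% qualified_ids
  contributors <- annotations[keep]
  n_used <- length(contributors)
  if (n_used < params$n_min) {
    return(base::structure(list(frame_id = frame_id, structure = struct,
                                status = "pending", mask = NULL,
                                contributor_ids = ids[keep],
                                vote_threshold_used = NA_integer_,
                                n_used = n_used),
                           class = "consensus_record"))
  }
  mv_used <- if (isTRUE(config$scale_mv) && n_used != params$n_min) {
    as.integer(ceiling(params$mv / params$n_min * n_used))
  } else {
    as.integer(params$mv)
  }
  fused <- majority_vote(lapply(contributors, `[[`, "mask"), mv_used)
  base::structure(list(frame_id = frame_id, structure = struct,
                       status = "complete", mask = fused,
                       contributor_ids = ids[keep],
                       vote_threshold_used = mv_used, n_used = n_used),
                  class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("<consensus %s/%s: %s, n_used=%d, mv=%s>\n", x$frame_id,
              x$structure, x$status, x$n_used,
              ifelse(is.na(x$vote_threshold_used), "-", x$vote_threshold_used)))
  invisible(x)
}
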