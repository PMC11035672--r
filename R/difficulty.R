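## Per-task difficulty index and review-threshold QA routing.
##
## DI = 1 - mean IoU of each contributing annotation against the final
## consensus mask (the consensus including that annotation's own vote; no
## leave-one-out). DI = 0 means unanimous agreement -- in particular a task
## where every annotator submitted "no finding", since empty masks are in
## perfect agreement. DI = 1 means no annotation shares a pixel with the
## consensus. Frames with DI above the review threshold RT are eligible for
## expert QA and sampled at a configurable Bernoulli rate.

#' Difficulty index of a consensus task
#'
#' @param masks list of the contributing annotation masks.
#' @param consensus the fused consensus `binary_mask`.
#' @return `di` in [0, 1]: `1 - mean(IoU(mask_i, consensus))`.
#' @export
difficulty_index <- function(masks, consensus) {
  if (length(masks) == 0)
    stop("difficulty_index: no contributing annotations", call. = FALSE)
  ious <- vapply(masks, mask_iou, numeric(1), ref = consensus)
  1 - mean(ious)
}

#' Build the difficulty/QA record for one consensus task
#'
#' @param record a complete `consensus_record`.
#' @param masks the contributing annotation masks (same order as
#'   `record$contributor_ids`).
#' @param config a [campaign_config()] supplying `rt` and
#'   `qa_sampling_rate`.
#' @param seed integer seed for the QA sampling draw.
#' @return a `difficulty_record`: `frame_id`, `structure`, `di`,
#'   `per_annotator_iou`, `qa_flagged` (`di > rt`), `qa_sampled`.
#' @export
difficulty_record <- function(record, masks, config, seed) {
  if (record$status != "complete")
    stop("difficulty_record: consensus is pending for (", record$frame_id,
         ", ", record$structure, ")", call. = FALSE)
  ious <- vapply(masks, mask_iou, numeric(1), ref = record$mask)
  di <- 1 - mean(ious)
  flag_for_review(
    base::structure(list(frame_id = record$frame_id,
                         structure = record$structure,
                         di = di, per_annotator_iou = ious,
                         qa_flagged = NA, qa_sampled = NA),
                    class = "difficulty_record"),
    rt = config$rt, sampling_rate = config$qa_sampling_rate, seed = seed)
}

#' Apply review-threshold QA routing to a difficulty record
#'
#' `qa_flagged = (di > rt)`; among flagged records, `qa_sampled` is a
#' Bernoulli(`sampling_rate`) draw, reproducible under the seed.
#'
#' @param record a `difficulty_record` (flags may be unset).
#' @param rt review threshold in [0, 1].
#' @param sampling_rate QA sampling rate in [0, 1].
#' @param seed integer seed.
#' @return the record with `qa_flagged` and `qa_sampled` set.
#' @export
flag_for_review <- function(record, rt, sampling_rate, seed) {
  if (rt < 0 || rt > 1) stop("rt must lie in [0, 1]", call. = FALSE)
  if (sampling_rate < 0 || sampling_rate > 1)
    stop("sampling_rate must lie in [0, 1]", call. = FALSE)
  record$qa_flagged <- record$di > rt
  record$qa_sampled <- record$qa_flagged &&
    with_seed(seed, stats::runif(1) < sampling_rate)
  record
}

#' Distribution summary of difficulty over a task set
#'
#' @param records list of `difficulty_record`s (one structure or mixed; use
#'   `by_structure = TRUE` to split).
#' @param by_structure summarize each structure separately.
#' @return a data.frame with `structure`, `n`, `median`, `q1`, `q3`,
#'   `zero_fraction` (share of DI = 0, i.e. unanimous -- typically
#'   "no finding" -- tasks).
#' @export
difficulty_profile <- function(records, by_structure = TRUE) {
  if (length(records) == 0) stop("difficulty_profile: no records", call. = FALSE)
  df <- data.frame(
    structure = vapply(records, `[[`, character(1), "structure"),
    di = vapply(records, `[[`, numeric(1), "di"),
    stringsAsFactors = FALSE)
  groups <- if (by_structure) split(df, df$structure) else list(all = df)
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]$di
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(structure = g, n = length(d), median = q[2], q1 = q[1],
               q3 = q[3], zero_fraction = mean(d == 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.difficulty_record <- function(x, ...) {
  cat(sprintf("<difficulty %s/%s: di=%.3f%s%s>\n", x$frame_id, x$structure,
              x$di, if (isTRUE(x$qa_flagged)) " QA-flagged" else "",
              if (isTRUE(x$qa_sampled)) " QA-sampled" else ""))
  invisible(x)
}
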