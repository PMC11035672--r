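## Annotator qualification and continuous performance monitoring.
##
## A candidate first annotates a fixed set of expert-annotated training
## tasks; the training score TS is the mean IoU against the expert masks
## and must clear `ts_min` before any ordinary annotation counts. Qualified
## annotators are then intermittently re-tested with running-gold tasks
## hidden in the stream; the running score RS is the rolling mean IoU over
## the most recent `rs_window` gold tests and must stay above `rs_min`.
## Disqualification is prospective: already-published consensus records are
## never rebuilt.

#' Create an annotator profile
#'
#' @param annotator_id identifier.
#' @param demographics_tag optional label, e.g. "non-MD", "MD",
#'   "surgical-MD".
#' @return an `annotator_profile` with undefined scores.
#' @export
annotator_profile <- function(annotator_id, demographics_tag = NA_character_) {
  base::structure(list(annotator_id = as.character(annotator_id),
                       training_scores = numeric(0),
                       ts = NA_real_,
                       running_scores = numeric(0),
                       rs = NA_real_,
                       qualified = FALSE,
                       demographics_tag = demographics_tag),
                  class = "annotator_profile")
}

#' Score a candidate on the training gold set
#'
#' TS is the arithmetic mean of per-task IoU between the candidate's
#' annotations and the matching expert reference masks. The protocol uses
#' exactly `config$n_training_gold` tasks (10 by default); any other count
#' is a protocol error.
#'
#' @param profile an `annotator_profile`.
#' @param annotations the candidate's training annotations (role
#'   `training_gold`), one per gold task.
#' @param references list of `expert_reference` records covering every
#'   (frame_id, structure) in `annotations`.
#' @param config a [campaign_config()].
#' @return the profile with `training_scores`, `ts` and `qualified` set.
#' @export
score_training <- function(profile, annotations, references, config) {
  if (length(annotations) != config$n_training_gold)
    stop("training requires exactly ", config$n_training_gold,
         " gold tasks; got ", length(annotations), call. = FALSE)
  ious <- vapply(annotations, function(a) {
    ref <- find_reference(references, a$frame_id, a$structure)
    mask_iou(a$mask, ref$mask)
  }, numeric(1))
  profile$training_scores <- ious
  profile$ts <- mean(ious)
  requalify(profile, config)
}

#' Update the running score with one gold-test result
#'
#' Appends the IoU of a running-gold annotation against its expert
#' reference and recomputes RS as the mean over the most recent
#' `config$rs_window` gold tests; qualification is re-evaluated after each
#' update.
#'
#' @param profile an `annotator_profile` with a defined TS.
#' @param annotation a `running_gold` annotation.
#' @param reference the matching `expert_reference`.
#' @param config a [campaign_config()].
#' @return the updated profile.
#' @export
update_running_score <- function(profile, annotation, reference, config) {
  if (annotation$role != "running_gold")
    stop("update_running_score expects a running_gold annotation", call. = FALSE)
  if (reference$frame_id != annotation$frame_id ||
      reference$structure != annotation$structure)
    stop("reference (", reference$frame_id, ", ", reference$structure,
         ") does not match annotation (", annotation$frame_id, ", ",
         annotation$structure, ")", call. = FALSE)
  profile$running_scores <- c(profile$running_scores,
                              mask_iou(annotation$mask, reference$mask))
  k <- min(length(profile$running_scores), config$rs_window)
  profile$rs <- mean(utils::tail(profile$running_scores, k))
  requalify(profile, config)
}

#' Is an annotator currently qualified?
#'
#' TRUE iff `ts >= ts_min` and, whenever a running score exists,
#' `rs >= rs_min`. An annotator who never completed training has no TS and
#' cannot be queried.
#'
#' @param profile an `annotator_profile`.
#' @param config a [campaign_config()].
#' @export
is_qualified <- function(profile, config) {
  if (is.na(profile$ts))
    stop("annotator '", profile$annotator_id, "' has no training score",
         call. = FALSE)
  profile$ts >= config$ts_min && (is.na(profile$rs) || profile$rs >= config$rs_min)
}

requalify <- function(profile, config) {
  profile$qualified <- is_qualified(profile, config)
  profile
}

#' Interleave running-gold tests into a task stream
#'
#' After each ordinary task, a running-gold task is inserted with
#' probability `1 / cadence` (so on average one gold test per `cadence`
#' ordinary tasks), drawn with replacement from the gold pool. The
#' insertion pattern is reproducible under the seed.
#'
#' @param tasks character (or list) of ordinary task ids, already ordered.
#' @param gold_pool non-empty vector/list of gold task ids.
#' @param cadence expected ordinary tasks per gold test, >= 1.
#' @param seed integer seed.
#' @return data.frame with columns `task` and `role`
#'   (`ordinary` / `running_gold`).
#' @export
interleave_gold <- function(tasks, gold_pool, cadence, seed) {
  if (length(gold_pool) == 0) stop("empty running-gold pool", call. = FALSE)
  if (cadence < 1) stop("cadence must be >= 1", call. = FALSE)
  with_seed(seed, {
    out_task <- character(0); out_role <- character(0)
    for (t in tasks) {
      out_task <- c(out_task, as.character(t)); out_role <- c(out_role, "ordinary")
      if (stats::runif(1) < 1 / cadence) {
        g <- gold_pool[[sample.int(length(gold_pool), 1)]]
        out_task <- c(out_task, as.character(g))
        out_role <- c(out_role, "running_gold")
      }
    }
    data.frame(task = out_task, role = out_role, stringsAsFactors = FALSE)
  })
}

find_reference <- function(references, frame_id, struct) {
  for (r in references)
    if (r$frame_id == frame_id && r$structure == struct) return(r)
  stop("no expert reference registered for (", frame_id, ", ", struct, ")",
       call. = FALSE)
}

#' @export
print.annotator_profile <- function(x, ...) {
  cat(sprintf("<annotator %s: ts=%s rs=%s %s>\n", x$annotator_id,
              ifelse(is.na(x$ts), "-", sprintf("%.3f", x$ts)),
              ifelse(is.na(x$rs), "-", sprintf("%.3f", x$rs)),
              if (x$qualified) "qualified" else "NOT qualified"))
  invisible(x)
}
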