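## End-to-end campaign orchestration and cost accounting.
##
## A campaign run takes a frame set and an annotation source (normally a
## simulated pool), trains and gates the annotators, routes tasks, fuses
## qualified annotations into consensus masks, scores difficulty, routes QA
## and tallies a ledger. Everything derives from the campaign seed, so two
## runs with the same configuration are identical down to the masks.
##
## Ledger conventions: gold-test annotations (training and running) are
## counted separately from consensus-contributing "individual" annotations,
## so a campaign with F frames, S structures and exactly n contributors per
## task reports F x S x n individual and F x S consensus annotations.

#' Run a simulated annotation campaign
#'
#' For each frame and structure, `n_min` currently-qualified annotators are
#' drawn at random to annotate the task (an annotator never sees the same
#' task twice); running-gold tests are interleaved into each annotator's
#' stream at rate `1 / rs_cadence` and update the running score, which can
#' disqualify the annotator prospectively. Tasks that cannot collect
#' `n_min` qualified annotations are reported pending, never fatal.
#'
#' @param n_frames number of ordinary frames to annotate.
#' @param pool an annotation source from [simulate_pool()].
#' @param config a [campaign_config()]; its `seed` drives the run.
#' @param n_running_gold_pool number of distinct running-gold frames kept
#'   aside per structure.
#' @return a `campaign_result`: lists `consensus`, `difficulty`,
#'   `profiles`, `ground_truth`, and the `ledger`.
#' @export
run_campaign <- function(n_frames, pool, config, n_running_gold_pool = 5) {
  structures <- names(config$structures)
  seed <- config$seed

  ## --- gold material: expert references are the scene's ground truth ----
  n_train_gold <- config$n_training_gold
  train_gold <- make_gold_tasks(pool, "tgold", n_train_gold, structures, seed)
  run_gold <- make_gold_tasks(pool, "rgold",
                              n_running_gold_pool * length(structures),
                              structures, seed)

  ## --- training phase ---------------------------------------------------
  profiles <- list()
  for (spec in pool$annotators) {
    aid <- spec$annotator_id
    prof <- annotator_profile(aid)
    anns <- lapply(train_gold, function(g)
      annotation(aid, g$frame_id, g$structure,
                 pool$annotate(aid, g$frame_id, g$structure, g$mask),
                 role = "training_gold"))
    refs <- lapply(train_gold, function(g)
      base::structure(list(frame_id = g$frame_id, structure = g$structure,
                           expert_id = "sim_expert", mask = g$mask),
                      class = "expert_reference"))
    profiles[[aid]] <- score_training(prof, anns, refs, config)
  }
  n_training_ann <- length(pool$annotators) * n_train_gold

  ## --- annotation phase -------------------------------------------------
  consensus <- list(); difficulty <- list(); ground_truth <- list()
  individual <- 0L; running_ann <- 0L; pending <- 0L
  flagged <- 0L; sampled <- 0L

  for (f in seq_len(n_frames)) {
    frame_id <- sprintf("frame_%05d", f)
    gt <- pool$ground_truth(f)
    ground_truth[[frame_id]] <- gt
    for (s in structures) {
      params <- structure_params(config, s)
      qualified <- names(profiles)[vapply(profiles, `[[`, logical(1), "qualified")]
      task_key <- paste(frame_id, s, sep = "/")
      if (length(qualified) < params$n_min) {
        pending <- pending + 1L
        consensus[[task_key]] <- base::structure(
          list(frame_id = frame_id, structure = s, status = "pending",
               mask = NULL, contributor_ids = character(0),
               vote_threshold_used = NA_integer_, n_used = 0L),
          class = "consensus_record")
        next
      }
      chosen <- with_seed(derive_seed(seed, "assign", frame_id, s), {
        qualified[sample.int(length(qualified), params$n_min)]
      })
      anns <- lapply(chosen, function(aid)
        annotation(aid, frame_id, s,
                   pool$annotate(aid, frame_id, s, gt[[s]])))
      individual <- individual + length(anns)

      rec <- build_consensus(anns, config, qualified_ids = chosen)
      consensus[[task_key]] <- rec
      masks <- lapply(anns, `[[`, "mask")
      difficulty[[task_key]] <- difficulty_record(
        rec, masks, config, derive_seed(seed, "qa", frame_id, s))
      if (difficulty[[task_key]]$qa_flagged) flagged <- flagged + 1L
      if (difficulty[[task_key]]$qa_sampled) sampled <- sampled + 1L

      ## interleaved running-gold tests for the contributors
      for (aid in chosen) {
        draw <- with_seed(derive_seed(seed, "cadence", aid, frame_id, s),
                          stats::runif(1))
        if (draw < 1 / config$rs_cadence) {
          g <- run_gold[[1 + derive_seed(seed, "pick", aid, frame_id, s) %%
                           length(run_gold)]]
          gold_ann <- annotation(
            aid, g$frame_id, g$structure,
            pool$annotate(aid, paste0(g$frame_id, "@", frame_id),
                          g$structure, g$mask),
            role = "running_gold")
          ref <- base::structure(list(frame_id = g$frame_id,
                                      structure = g$structure,
                                      expert_id = "sim_expert", mask = g$mask),
                                 class = "expert_reference")
          profiles[[aid]] <- update_running_score(profiles[[aid]], gold_ann,
                                                  ref, config)
          running_ann <- running_ann + 1L
        }
      }
    }
  }

  hours <- expert_hours_saved(n_frames, config$expert_seconds_per_frame)
  ledger <- base::structure(list(
    frames = as.integer(n_frames),
    structures = length(structures),
    individual_annotations = individual,
    consensus_annotations = sum(vapply(consensus, function(x)
      x$status == "complete", logical(1))),
    pending_tasks = pending,
    training_gold_annotations = as.integer(n_training_ann),
    running_gold_annotations = running_ann,
    qa_flagged = flagged,
    qa_sampled = sampled,
    expert_hours_saved = hours$rounded,
    expert_hours_saved_raw = hours$raw,
    frames_per_expert_day = frames_per_expert_day(
      config$experts_available, config$expert_hours_per_day,
      config$expert_seconds_per_frame)),
    class = "campaign_ledger")

  base::structure(list(consensus = consensus, difficulty = difficulty,
                       profiles = profiles, ground_truth = ground_truth,
                       ledger = ledger, config = config),
                  class = "campaign_result")
}

make_gold_tasks <- function(pool, tag, n, structures, seed) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- structures[1 + (i - 1) %% length(structures)]
    fid <- sprintf("%s_%03d", tag, i)
    # gold truths come from a dedicated stream; force a visible structure so
    # gold tests discriminate (an all-empty gold task scores everyone 1)
    gt <- NULL
    for (attempt in 1:25) {
      cand <- make_ground_truth(pool$scene, paste0(tag, "_", i, "_", attempt),
                                derive_seed(seed, "goldgt", tag))
      if (!is_no_finding(cand[[s]])) { gt <- cand[[s]]; break }
    }
    if (is.null(gt)) gt <- cand[[s]]
    out[[i]] <- list(frame_id = fid, structure = s, mask = gt)
  }
  out
}

# round half up: the reporting convention for headline hours and percentages
round_half_up <- function(x) floor(x + 0.5)

#' Expert hours saved by crowdsourcing a frame set
#'
#' `frames * seconds_per_frame / 3600`, reported raw and rounded half-up to
#' whole hours (the headline convention).
#'
#' @param frames number of frames annotated by the crowd.
#' @param seconds_per_frame measured mean expert time per frame.
#' @return list with `raw` and `rounded` hours.
#' @export
expert_hours_saved <- function(frames, seconds_per_frame) {
  if (frames < 0) stop("frames must be >= 0", call. = FALSE)
  if (seconds_per_frame <= 0)
    stop("seconds_per_frame must be positive", call. = FALSE)
  raw <- frames * seconds_per_frame / 3600
  list(raw = raw, rounded = round_half_up(raw))
}

#' Expert annotation throughput in frames per day
#'
#' `experts * hours_per_day * 3600 / seconds_per_frame`, rounded to the
#' nearest frame.
#'
#' @param experts number of available experts.
#' @param hours_per_day annotation hours per expert per day.
#' @param seconds_per_frame mean expert time per frame.
#' @return integer frames per day.
#' @export
frames_per_expert_day <- function(experts, hours_per_day, seconds_per_frame) {
  if (experts <= 0 || hours_per_day <= 0 || seconds_per_frame <= 0)
    stop("all inputs must be positive", call. = FALSE)
  as.integer(round_half_up(experts * hours_per_day * 3600 / seconds_per_frame))
}

#' Annotator demographics summary
#'
#' Counts per demographics tag with integer percentages (rounded half-up),
#' e.g. the share of annotators self-identifying as MDs.
#'
#' @param profiles list of `annotator_profile`s (or a character vector of
#'   tags).
#' @return data.frame with `tag`, `count`, `percent`; zero rows when empty.
#' @export
demographics_summary <- function(profiles) {
  tags <- if (is.character(profiles)) profiles
          else vapply(profiles, `[[`, character(1), "demographics_tag")
  if (length(tags) == 0)
    return(data.frame(tag = character(0), count = integer(0),
                      percent = integer(0), stringsAsFactors = FALSE))
  tags[is.na(tags)] <- "unknown"
  tab <- table(tags)
  data.frame(tag = names(tab), count = as.integer(tab),
             percent = as.integer(round_half_up(100 * as.integer(tab) /
                                                  length(tags))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.campaign_ledger <- function(x, ...) {
  cat("campaign ledger\n")
  cat(sprintf("  frames x structures : %d x %d\n", x$frames, x$structures))
  cat(sprintf("  individual annotations : %d\n", x$individual_annotations))
  cat(sprintf("  consensus annotations  : %d (pending %d)\n",
              x$consensus_annotations, x$pending_tasks))
  cat(sprintf("  gold annotations       : %d training, %d running\n",
              x$training_gold_annotations, x$running_gold_annotations))
  cat(sprintf("  QA flagged/sampled     : %d / %d\n", x$qa_flagged, x$qa_sampled))
  cat(sprintf("  expert hours saved     : %d (%.2f raw)\n",
              x$expert_hours_saved, x$expert_hours_saved_raw))
  cat(sprintf("  frames per expert day  : %d\n", x$frames_per_expert_day))
  invisible(x)
}
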