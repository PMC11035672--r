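## Batch (directory / manifest) entry points behind the command-line verbs.
## Masks travel as single-channel PNGs, tables as UTF-8 CSVs, ledgers as
## JSON; everything here is a thin file-format layer over the core modules.

#' Evaluate a directory of predicted masks against references
#'
#' Pairs files by name (`<frame>__<structure>.png` or any identical
#' basenames) and writes one row of metrics per pair plus a mean +/- sd
#' summary row per structure.
#'
#' @param pred_dir,ref_dir directories of PNG masks with matching names.
#' @param out_csv output report path (optional).
#' @return the report data.frame, invisibly when written.
#' @export
eval_mask_dirs <- function(pred_dir, ref_dir, out_csv = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "\\.png$"))
  if (length(preds) == 0) stop("no PNG masks in ", pred_dir, call. = FALSE)
  missing <- preds[!file.exists(file.path(ref_dir, preds))]
  if (length(missing))
    stop("reference masks missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(preds, function(f) {
    rep <- evaluate_masks(read_mask(file.path(pred_dir, f)),
                          read_mask(file.path(ref_dir, f)))
    parts <- strsplit(tools::file_path_sans_ext(f), "__", fixed = TRUE)[[1]]
    data.frame(frame_id = parts[1],
               structure = if (length(parts) > 1) parts[2] else "all",
               kind = "frame", iou = rep$iou, f1 = rep$f1,
               accuracy = rep$accuracy, sensitivity = rep$sensitivity,
               specificity = rep$specificity, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  for (s in unique(report$structure)) {
    sub <- report[report$structure == s & report$kind == "frame", ]
    report <- rbind(report, data.frame(
      frame_id = sprintf("mean_of_%d", nrow(sub)), structure = s,
      kind = "summary", iou = mean(sub$iou), f1 = mean(sub$f1),
      accuracy = mean(sub$accuracy), sensitivity = mean(sub$sensitivity),
      specificity = mean(sub$specificity), stringsAsFactors = FALSE))
  }
  if (!is.null(out_csv)) {
    utils::write.csv(report, out_csv, row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Build consensus masks from a campaign manifest
#'
#' Groups the manifest's ordinary annotations by (frame, structure), fuses
#' each group with the configured (n, MV), and writes one consensus PNG per
#' completed task plus a `consensus.csv` status table. Annotator
#' qualification can be supplied as a vector of qualified ids (e.g. from
#' [gate_from_manifest()]); by default all contributors count.
#'
#' @param manifest_csv manifest path (see [load_manifest()]).
#' @param config a [campaign_config()].
#' @param out_dir output directory (created if needed).
#' @param qualified_ids optional character vector of qualified annotators.
#' @return the consensus status data.frame, invisibly.
#' @export
consensus_from_manifest <- function(manifest_csv, config, out_dir,
                                    qualified_ids = NULL) {
  anns <- load_manifest(manifest_csv)
  anns <- Filter(function(a) a$role == "ordinary", anns)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  key <- vapply(anns, function(a) paste(a$frame_id, a$structure, sep = "\x1f"),
                character(1))
  rows <- lapply(split(anns, key), function(group) {
    rec <- build_consensus(group, config, qualified_ids = qualified_ids)
    if (rec$status == "complete")
      write_mask(rec$mask, file.path(out_dir, sprintf("%s__%s.png",
                                                      rec$frame_id,
                                                      rec$structure)))
    data.frame(frame_id = rec$frame_id, structure = rec$structure,
               status = rec$status, n_used = rec$n_used,
               mv = rec$vote_threshold_used,
               contributors = paste(rec$contributor_ids, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  status <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  status <- status[order(status$frame_id, status$structure), ]
  utils::write.csv(status, file.path(out_dir, "consensus.csv"),
                   row.names = FALSE)
  invisible(status)
}

#' Gate annotators from manifest gold tasks
#'
#' Scores every annotator's `training_gold` rows (TS = mean IoU against the
#' expert references) and `running_gold` rows (RS over the rolling window,
#' in manifest order) and writes a `profiles.csv`.
#'
#' @param manifest_csv manifest path.
#' @param refs_csv expert reference table path (see [load_expert_refs()]).
#' @param config a [campaign_config()].
#' @param out_csv optional output path.
#' @return data.frame `annotator_id, ts, rs, qualified, n_training,
#'   n_running`.
#' @export
gate_from_manifest <- function(manifest_csv, refs_csv, config, out_csv = NULL) {
  anns <- load_manifest(manifest_csv)
  refs <- load_expert_refs(refs_csv)
  ids <- unique(vapply(anns, `[[`, character(1), "annotator_id"))
  rows <- lapply(ids, function(aid) {
    mine <- Filter(function(a) a$annotator_id == aid, anns)
    train <- Filter(function(a) a$role == "training_gold", mine)
    running <- Filter(function(a) a$role == "running_gold", mine)
    prof <- annotator_profile(aid)
    if (length(train) != config$n_training_gold) {
      # incomplete training: no TS, never qualified
      ts <- NA_real_; rs <- NA_real_; qualified <- FALSE
      n_run <- length(running)
    } else {
      prof <- score_training(prof, train, refs, config)
      for (g in running) {
        ref <- find_reference(refs, g$frame_id, g$structure)
        prof <- update_running_score(prof, g, ref, config)
      }
      ts <- prof$ts; rs <- prof$rs; qualified <- prof$qualified
      n_run <- length(running)
    }
    data.frame(annotator_id = aid, ts = ts, rs = rs, qualified = qualified,
               n_training = length(train), n_running = n_run,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Score difficulty for consensus masks built from a manifest
#'
#' Recomputes per-task DI from the individual annotations in the manifest
#' against the consensus PNGs in `consensus_dir`, applies RT routing, and
#' writes `difficulty.csv`.
#'
#' @param consensus_dir directory produced by [consensus_from_manifest()].
#' @param manifest_csv manifest path.
#' @param config a [campaign_config()].
#' @param out_csv optional output path.
#' @return data.frame `frame_id, structure, di, qa_flagged, qa_sampled`.
#' @export
difficulty_from_consensus <- function(consensus_dir, manifest_csv, config,
                                      out_csv = NULL) {
  anns <- Filter(function(a) a$role == "ordinary", load_manifest(manifest_csv))
  key <- vapply(anns, function(a) paste(a$frame_id, a$structure, sep = "\x1f"),
                character(1))
  rows <- lapply(split(anns, key), function(group) {
    fid <- group[[1]]$frame_id; s <- group[[1]]$structure
    path <- file.path(consensus_dir, sprintf("%s__%s.png", fid, s))
    if (!file.exists(path)) return(NULL)  # pending task: no consensus mask
    cons <- read_mask(path)
    di <- difficulty_index(lapply(group, `[[`, "mask"), cons)
    rec <- flag_for_review(
      base::structure(list(frame_id = fid, structure = s, di = di,
                           per_annotator_iou = NULL, qa_flagged = NA,
                           qa_sampled = NA),
                      class = "difficulty_record"),
      rt = config$rt, sampling_rate = config$qa_sampling_rate,
      seed = derive_seed(config$seed, "qa", fid, s))
    data.frame(frame_id = fid, structure = s, di = di,
               qa_flagged = rec$qa_flagged, qa_sampled = rec$qa_sampled,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out <- out[order(out$frame_id, out$structure), ]
    rownames(out) <- NULL
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Emit a simulated campaign's raw material to disk
#'
#' Writes per-annotation PNG masks, ground-truth reference masks, the
#' campaign manifest and an expert-reference table, all in the package's
#' file conventions, so the file-level verbs can be exercised end to end.
#'
#' @param pool a [simulate_pool()] source.
#' @param n_frames frames to generate.
#' @param out_dir destination directory.
#' @return path of the manifest, invisibly.
#' @export
simulate_to_dir <- function(pool, n_frames, out_dir) {
  masks_dir <- file.path(out_dir, "masks")
  truth_dir <- file.path(out_dir, "truth")
  dir.create(masks_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(truth_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); refs <- list()
  for (f in seq_len(n_frames)) {
    fid <- sprintf("frame_%05d", f)
    gt <- pool$ground_truth(f)
    for (s in names(gt)) {
      ref_name <- sprintf("%s__%s.png", fid, s)
      write_mask(gt[[s]], file.path(truth_dir, ref_name))
      refs[[length(refs) + 1]] <- data.frame(
        frame_id = fid, structure = s, expert_id = "sim_truth",
        mask_path = file.path("truth", ref_name), stringsAsFactors = FALSE)
      for (spec in pool$annotators) {
        aid <- spec$annotator_id
        mask <- pool$annotate(aid, fid, s, gt[[s]])
        name <- sprintf("%s__%s__%s.png", fid, s, aid)
        write_mask(mask, file.path(masks_dir, name))
        rows[[length(rows) + 1]] <- data.frame(
          annotator_id = aid, frame_id = fid, structure = s,
          role = "ordinary", mask_path = file.path("masks", name),
          elapsed_s = round(pool$elapsed(aid, fid, s), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  utils::write.csv(do.call(rbind, refs), file.path(out_dir, "experts.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write campaign results to a run directory
#'
#' Consensus PNGs plus `consensus.csv`, `difficulty.csv`, `profiles.csv`
#' and `ledger.json` (requires jsonlite).
#'
#' @param result a `campaign_result` from [run_campaign()].
#' @param out_dir destination directory.
#' @return `out_dir`, invisibly.
#' @export
write_campaign <- function(result, out_dir) {
  cons_dir <- file.path(out_dir, "consensus")
  dir.create(cons_dir, showWarnings = FALSE, recursive = TRUE)
  cons_rows <- lapply(result$consensus, function(rec) {
    if (rec$status == "complete")
      write_mask(rec$mask, file.path(cons_dir, sprintf("%s__%s.png",
                                                       rec$frame_id,
                                                       rec$structure)))
    data.frame(frame_id = rec$frame_id, structure = rec$structure,
               status = rec$status, n_used = rec$n_used,
               mv = rec$vote_threshold_used,
               contributors = paste(rec$contributor_ids, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, c(cons_rows, list(make.row.names = FALSE))),
                   file.path(out_dir, "consensus.csv"), row.names = FALSE)
  diff_rows <- lapply(result$difficulty, function(d)
    data.frame(frame_id = d$frame_id, structure = d$structure, di = d$di,
               qa_flagged = d$qa_flagged, qa_sampled = d$qa_sampled,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, c(diff_rows, list(make.row.names = FALSE))),
                   file.path(out_dir, "difficulty.csv"), row.names = FALSE)
  prof_rows <- lapply(result$profiles, function(p)
    data.frame(annotator_id = p$annotator_id, ts = p$ts, rs = p$rs,
               qualified = p$qualified,
               n_training = length(p$training_scores),
               n_running = length(p$running_scores), stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, c(prof_rows, list(make.row.names = FALSE))),
                   file.path(out_dir, "profiles.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(result$ledger),
                         file.path(out_dir, "ledger.json"), auto_unbox = TRUE)
  }
  invisible(out_dir)
}
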