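## Campaign configuration: the five crowdsourcing control parameters
## (TS, RS, n, MV, RT) plus the auxiliary knobs the protocol leaves open
## (running-score cadence and window, QA sampling rate, seed) and the
## expert-time accounting constants.

#' Campaign configuration
#'
#' @param structures named list, one entry per structure label, each a list
#'   with `n_min` (minimum qualified annotations per task) and `mv`
#'   (absolute majority-vote threshold). The default mirrors the shipped
#'   bowel / abdominal-wall task set: bowel 4-of-5, abdominal wall 2-of-5.
#' @param ts_min minimum training score (mean IoU over the training gold
#'   set) required before any annotation counts. The study platform's cutoff
#'   is not public; 0.5 is a conservative, overridable default.
#' @param rs_min minimum running score (rolling mean IoU over recent gold
#'   tests) to stay qualified.
#' @param n_training_gold number of expert-annotated training tasks each
#'   candidate must complete (10 in the protocol).
#' @param rs_cadence expected number of ordinary tasks per interleaved
#'   running-gold test (Bernoulli insertion at rate 1/cadence).
#' @param rs_window number of most recent gold tests in the running score.
#' @param rt review threshold: difficulty-index cutoff above which frames
#'   are eligible for expert QA (0.4 in the protocol).
#' @param qa_sampling_rate Bernoulli sampling rate among flagged frames.
#' @param expert_seconds_per_frame measured mean expert annotation time for
#'   one frame, both structures (120.3 s).
#' @param experts_available,expert_hours_per_day expert capacity used for
#'   throughput accounting (4 experts at one hour per day).
#' @param scale_mv when a task attracts more than `n_min` qualified
#'   annotations, rescale MV to preserve the voting fraction (default TRUE).
#' @param seed campaign master seed; all sub-streams derive from it.
#' @return a validated `campaign_config` list.
#' @export
campaign_config <- function(structures = list(
                              bowel = list(n_min = 5, mv = 4),
                              abdominal_wall = list(n_min = 5, mv = 2)),
                            ts_min = 0.5, rs_min = 0.5,
                            n_training_gold = 10,
                            rs_cadence = 20, rs_window = 10,
                            rt = 0.4, qa_sampling_rate = 0.1,
                            expert_seconds_per_frame = 120.3,
                            experts_available = 4, expert_hours_per_day = 1,
                            scale_mv = TRUE, seed = 1L) {
  cfg <- list(structures = structures, ts_min = ts_min, rs_min = rs_min,
              n_training_gold = as.integer(n_training_gold),
              rs_cadence = as.integer(rs_cadence),
              rs_window = as.integer(rs_window),
              rt = rt, qa_sampling_rate = qa_sampling_rate,
              expert_seconds_per_frame = expert_seconds_per_frame,
              experts_available = experts_available,
              expert_hours_per_day = expert_hours_per_day,
              scale_mv = isTRUE(scale_mv), seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "campaign_config"
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$structures) == 0 || is.null(names(cfg$structures)))
    stop("config: `structures` must be a named list", call. = FALSE)
  for (s in names(cfg$structures)) {
    p <- cfg$structures[[s]]
    if (is.null(p$n_min) || is.null(p$mv) || p$n_min < 1 ||
        p$mv < 1 || p$mv > p$n_min)
      stop("config: structure '", s, "' needs 1 <= mv <= n_min", call. = FALSE)
  }
  fracs <- c(ts_min = cfg$ts_min, rs_min = cfg$rs_min, rt = cfg$rt,
             qa_sampling_rate = cfg$qa_sampling_rate)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad))
    stop("config: ", paste(bad, collapse = ", "), " must lie in [0, 1]",
         call. = FALSE)
  if (cfg$n_training_gold < 1 || cfg$rs_cadence < 1 || cfg$rs_window < 1)
    stop("config: counts must be >= 1", call. = FALSE)
  if (cfg$expert_seconds_per_frame <= 0)
    stop("config: expert_seconds_per_frame must be positive", call. = FALSE)
  invisible(cfg)
}

structure_params <- function(config, struct) {
  p <- config$structures[[struct]]
  if (is.null(p))
    stop("no campaign parameters configured for structure '", struct, "'",
         call. = FALSE)
  p
}

#' Read a campaign configuration from a YAML file
#'
#' The YAML mirrors the [campaign_config()] arguments; missing keys fall
#' back to the defaults.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_config requires the 'yaml' package", call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(campaign_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config '", path, "': unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(campaign_config, raw)
}

#' @export
print.campaign_config <- function(x, ...) {
  cat("campaign_config\n")
  for (s in names(x$structures))
    cat(sprintf("  %s: n_min=%d mv=%d\n", s, x$structures[[s]]$n_min,
                x$structures[[s]]$mv))
  cat(sprintf("  ts_min=%.2f rs_min=%.2f training_gold=%d rs: 1/%d window=%d\n",
              x$ts_min, x$rs_min, x$n_training_gold, x$rs_cadence, x$rs_window))
  cat(sprintf("  rt=%.2f qa_rate=%.2f seed=%d\n", x$rt, x$qa_sampling_rate, x$seed))
  invisible(x)
}
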