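## Synthetic scenes and skill-parameterized synthetic annotators.
##
## The generator stands in for surgical video frames: per structure, a
## frame either lacks the structure (yielding a "no finding" ground truth)
## or contains a union of random discs. Annotators degrade the truth with a
## symmetric boundary-error model (random disc dilation/erosion plus
## boundary pixel flips), may miss a visible structure entirely, or may be
## spammers who ignore the truth altogether. All draws derive
## hierarchically from (campaign seed, annotator, frame) so streams are
## stable when the pool grows.

#' Scene specification for the synthetic frame generator
#'
#' @param width,height frame size in pixels.
#' @param structures named list, one entry per structure label, each with
#'   `presence_probability` (chance the structure appears in a frame),
#'   `blob_count` length-2 integer range, and `blob_radius` length-2 range
#'   in pixels.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(width = 64, height = 64,
                       structures = list(
                         bowel = list(presence_probability = 0.8,
                                      blob_count = c(1, 3),
                                      blob_radius = c(6, 14)),
                         abdominal_wall = list(presence_probability = 0.7,
                                               blob_count = c(1, 2),
                                               blob_radius = c(8, 16)))) {
  for (s in names(structures)) {
    p <- structures[[s]]
    if (p$presence_probability < 0 || p$presence_probability > 1)
      stop("scene_spec: presence_probability for '", s, "' not in [0,1]",
           call. = FALSE)
    if (min(p$blob_radius) < 1)
      stop("scene_spec: blob_radius for '", s, "' must be >= 1", call. = FALSE)
    if (max(p$blob_radius) > min(width, height))
      stop("scene_spec: blob_radius for '", s, "' exceeds the frame",
           call. = FALSE)
  }
  base::structure(list(width = as.integer(width), height = as.integer(height),
                       structures = structures),
                  class = "scene_spec")
}

#' Annotator behaviour specification
#'
#' @param annotator_id identifier.
#' @param boundary_jitter radius bound of the random disc
#'   dilation/erosion applied to the truth (pixels; 0 = faithful boundary).
#' @param pixel_noise flip probability for pixels in the boundary band.
#' @param miss_probability chance of submitting "no finding" although the
#'   structure is visible.
#' @param spammer if TRUE the annotator ignores the ground truth and
#'   submits a random blob (or nothing).
#' @param mean_elapsed_s mean of the log-normal annotation-time model.
#' @return an `annotator_spec`.
#' @export
annotator_spec <- function(annotator_id, boundary_jitter = 1,
                           pixel_noise = 0.02, miss_probability = 0.02,
                           spammer = FALSE, mean_elapsed_s = 40) {
  stopifnot(boundary_jitter >= 0, pixel_noise >= 0, pixel_noise <= 1,
            miss_probability >= 0, miss_probability <= 1)
  base::structure(list(annotator_id = as.character(annotator_id),
                       boundary_jitter = boundary_jitter,
                       pixel_noise = pixel_noise,
                       miss_probability = miss_probability,
                       spammer = isTRUE(spammer),
                       mean_elapsed_s = mean_elapsed_s),
                  class = "annotator_spec")
}

#' Generate ground-truth masks for one frame
#'
#' Deterministic in (seed, frame_index): with the structure's presence
#' probability the mask is a union of uniformly placed random discs,
#' otherwise empty ("no finding" truth).
#'
#' @param spec a [scene_spec()].
#' @param frame_index frame number (any integer label).
#' @param seed scene seed.
#' @return named list of `binary_mask`, one per structure.
#' @export
make_ground_truth <- function(spec, frame_index, seed) {
  out <- list()
  for (s in names(spec$structures)) {
    p <- spec$structures[[s]]
    out[[s]] <- with_seed(derive_seed(seed, "gt", frame_index, s), {
      if (stats::runif(1) >= p$presence_probability) {
        mask_from_coords(spec$height, spec$width)
      } else {
        k <- sample(p$blob_count[1]:p$blob_count[2], 1)
        m <- matrix(FALSE, spec$height, spec$width)
        for (i in seq_len(k)) {
          r <- stats::runif(1, p$blob_radius[1], p$blob_radius[2])
          m <- m | disc_mask(spec$height, spec$width,
                             center_row = stats::runif(1, 1, spec$height),
                             center_col = stats::runif(1, 1, spec$width),
                             radius = r)
        }
        binary_mask(m)
      }
    })
  }
  out
}

#' Simulate one annotator's mask for a ground-truth mask
#'
#' Spammers return a random disc (ignoring the truth). Otherwise, with
#' `miss_probability` the annotation is "no finding"; else the truth is
#' dilated or eroded by a disc whose radius is drawn uniformly from
#' `{-jitter, ..., +jitter}` (negative = erosion) and pixels in the
#' boundary band are flipped at rate `pixel_noise`.
#'
#' @param gt the ground-truth `binary_mask`.
#' @param spec an [annotator_spec()].
#' @param seed integer seed for this (annotator, task) draw.
#' @return a `binary_mask`.
#' @export
simulate_annotation <- function(gt, spec, seed) {
  m <- as_mask_matrix(gt)
  with_seed(seed, {
    if (spec$spammer) {
      # random blob roughly in the scale of plausible structures
      r <- stats::runif(1, 3, max(4, min(dim(m)) / 3))
      return(binary_mask(disc_mask(nrow(m), ncol(m),
                                   stats::runif(1, 1, nrow(m)),
                                   stats::runif(1, 1, ncol(m)), r)))
    }
    if (any(m) && stats::runif(1) < spec$miss_probability)
      return(binary_mask(matrix(FALSE, nrow(m), ncol(m))))
    out <- m
    if (spec$boundary_jitter > 0) {
      j <- spec$boundary_jitter
      r <- sample(seq.int(-j, j), 1)
      out <- if (r > 0) as_mask_matrix(dilate_disc(out, r))
             else if (r < 0) as_mask_matrix(erode_disc(out, -r))
             else out
    }
    if (spec$pixel_noise > 0) {
      band <- which(boundary_band(out))
      if (length(band)) {
        flip <- band[stats::runif(length(band)) < spec$pixel_noise]
        out[flip] <- !out[flip]
      }
    }
    binary_mask(out)
  })
}

#' Simulated annotation pool
#'
#' Wraps a set of annotator specs and a scene into an annotation source
#' compatible with [run_campaign()]: ground truth per frame plus on-demand
#' per-annotator annotations, each draw independently seeded from
#' (campaign seed, annotator, task).
#'
#' @param annotators list of [annotator_spec()]s.
#' @param scene a [scene_spec()].
#' @param seed campaign seed used to derive all sub-streams.
#' @return a `sim_pool`: list with `annotators`, `scene`, `seed`,
#'   `$ground_truth(frame_index)` and
#'   `$annotate(annotator_id, frame_id, structure, gt_mask)`.
#' @export
simulate_pool <- function(annotators, scene, seed) {
  ids <- vapply(annotators, `[[`, character(1), "annotator_id")
  if (anyDuplicated(ids)) stop("duplicate annotator ids in pool", call. = FALSE)
  names(annotators) <- ids
  pool <- list(
    annotators = annotators,
    scene = scene,
    seed = as.integer(seed),
    ground_truth = function(frame_index)
      make_ground_truth(scene, frame_index, seed),
    annotate = function(annotator_id, frame_id, structure, gt_mask) {
      spec <- annotators[[annotator_id]]
      if (is.null(spec)) stop("unknown annotator: ", annotator_id, call. = FALSE)
      simulate_annotation(gt_mask, spec,
                          derive_seed(seed, "ann", annotator_id, frame_id,
                                      structure))
    },
    elapsed = function(annotator_id, frame_id, structure) {
      spec <- annotators[[annotator_id]]
      with_seed(derive_seed(seed, "time", annotator_id, frame_id, structure),
                stats::rlnorm(1, meanlog = log(spec$mean_elapsed_s), sdlog = 0.4))
    })
  class(pool) <- "sim_pool"
  pool
}

#' Default mixed-skill annotator pool
#'
#' Convenience constructor: `n_good` careful annotators (1 px jitter),
#' `n_sloppy` noisier ones (2-3 px jitter, higher miss rate), and
#' `n_spam` spammers.
#'
#' @param n_good,n_sloppy,n_spam pool composition.
#' @return list of [annotator_spec()]s.
#' @export
default_pool_specs <- function(n_good = 4, n_sloppy = 2, n_spam = 0) {
  specs <- list()
  for (i in seq_len(n_good))
    specs <- c(specs, list(annotator_spec(sprintf("good_%02d", i),
                                          boundary_jitter = 1,
                                          pixel_noise = 0.02,
                                          miss_probability = 0.01)))
  for (i in seq_len(n_sloppy))
    specs <- c(specs, list(annotator_spec(sprintf("sloppy_%02d", i),
                                          boundary_jitter = 3,
                                          pixel_noise = 0.08,
                                          miss_probability = 0.10)))
  for (i in seq_len(n_spam))
    specs <- c(specs, list(annotator_spec(sprintf("spam_%02d", i),
                                          spammer = TRUE)))
  specs
}
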