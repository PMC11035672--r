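# Shared fixtures: all masks are generated in code at test time.

random_mask <- function(h, w, p = 0.5) {
  binary_mask(matrix(stats::runif(h * w) < p, h, w))
}

# brute-force per-pixel confusion oracle: intentionally naive, loops pixels
oracle_confusion <- function(pred, ref) {
  p <- unclass(pred); r <- unclass(ref)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(p)) {
    if (p[[i]] && r[[i]]) tp <- tp + 1L
    else if (p[[i]] && !r[[i]]) fp <- fp + 1L
    else if (!p[[i]] && r[[i]]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_metrics <- function(pred, ref) {
  cc <- oracle_confusion(pred, ref)
  safe <- function(num, den, empty) if (den == 0) empty else num / den
  list(iou = safe(cc$tp, cc$tp + cc$fp + cc$fn, 1),
       f1 = safe(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn, 1),
       accuracy = (cc$tp + cc$tn) / sum(unlist(cc)),
       sensitivity = safe(cc$tp, cc$tp + cc$fn, 1),
       specificity = safe(cc$tn, cc$tn + cc$fp, 1))
}

# all 512 3x3 masks, indexed by bit pattern
all_3x3_masks <- function() {
  lapply(0:511, function(b) binary_mask(matrix(bitwAnd(b, 2^(0:8)) > 0, 3, 3)))
}

# a quick perfect-annotator pool for ledger-shape tests
perfect_pool <- function(n = 5, scene = scene_spec(width = 16, height = 16),
                         seed = 1) {
  specs <- lapply(seq_len(n), function(i)
    annotator_spec(sprintf("perfect_%02d", i), boundary_jitter = 0,
                   pixel_noise = 0, miss_probability = 0))
  simulate_pool(specs, scene, seed)
}

small_config <- function(...) {
  campaign_config(ts_min = 0.5, rs_min = 0.5, ...)
}
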