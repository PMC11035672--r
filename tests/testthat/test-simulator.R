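test_that("morphology: disc dilation/erosion behave on a known square", {
  sq <- mask_from_coords(9, 9, as.matrix(expand.grid(3:5, 3:5)))
  d1 <- dilate_disc(sq, 1)
  # plus-shaped growth: 9 + 4 edges of 3
  expect_equal(sum(d1), 9 + 12)
  e1 <- erode_disc(sq, 1)
  expect_equal(mask_coords(e1), cbind(row = 4L, col = 4L))
  # duality and identity
  expect_equal(dilate_disc(sq, 0), sq)
  expect_true(all(unclass(erode_disc(dilate_disc(sq, 1), 1)) >= unclass(sq)))
  expect_true(is_no_finding(erode_disc(mask_from_coords(4, 4, rbind(c(1, 1))), 1)))
  expect_true(is_no_finding(dilate_disc(mask_from_coords(5, 5), 2)))
})

test_that("morphology agrees with a brute-force distance oracle", {
  # independent definition: dilation by a disc of radius r marks every pixel
  # within Euclidean distance r of some foreground pixel
  oracle_dilate <- function(mask, r) {
    m <- unclass(mask)
    fg <- which(m, arr.ind = TRUE)
    out <- matrix(FALSE, nrow(m), ncol(m))
    if (nrow(fg)) {
      for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
        d2 <- (fg[, 1] - i)^2 + (fg[, 2] - j)^2
        if (any(d2 <= r^2)) out[i, j] <- TRUE
      }
    }
    binary_mask(out)
  }
  with_seed(61, {
    for (k in 1:10) {
      m <- random_mask(12, 12, runif(1, 0.05, 0.4))
      for (r in 1:3) {
        expect_identical(dilate_disc(m, r), oracle_dilate(m, r))
        # erosion via complement duality of the oracle
        expect_identical(unclass(erode_disc(m, r)),
                         !unclass(oracle_dilate(binary_mask(!unclass(m)), r)))
      }
    }
  })
})

test_that("make_ground_truth respects presence probability and determinism", {
  absent <- scene_spec(width = 16, height = 16,
                       structures = list(bowel = list(
                         presence_probability = 0, blob_count = c(1, 1),
                         blob_radius = c(2, 3))))
  for (i in 1:20)
    expect_true(is_no_finding(make_ground_truth(absent, i, 1)$bowel))

  always <- scene_spec(width = 16, height = 16,
                       structures = list(bowel = list(
                         presence_probability = 1, blob_count = c(1, 1),
                         blob_radius = c(3, 3))))
  m1 <- make_ground_truth(always, 5, 42)$bowel
  m2 <- make_ground_truth(always, 5, 42)$bowel
  expect_identical(m1, m2)
  expect_false(is_no_finding(m1))
  expect_false(identical(m1, make_ground_truth(always, 6, 42)$bowel))

  # empirical presence fraction within 3 sigma of 0.7 over 1000 frames
  p07 <- scene_spec(width = 8, height = 8,
                    structures = list(bowel = list(
                      presence_probability = 0.7, blob_count = c(1, 1),
                      blob_radius = c(2, 2))))
  present <- sum(!vapply(1:1000, function(i)
    is_no_finding(make_ground_truth(p07, i, 9)$bowel), logical(1)))
  expect_lt(abs(present - 700), 3 * sqrt(1000 * 0.7 * 0.3))

  expect_error(scene_spec(width = 8, height = 8,
                          structures = list(b = list(
                            presence_probability = 1, blob_count = c(1, 1),
                            blob_radius = c(2, 20)))), "exceeds the frame")
})

test_that("simulate_annotation models the skill spectrum", {
  gt <- binary_mask(with_seed(1, unclass(dilate_disc(
    mask_from_coords(32, 32, rbind(c(15, 15))), 8))))

  perfect <- annotator_spec("p", boundary_jitter = 0, pixel_noise = 0,
                            miss_probability = 0)
  expect_identical(simulate_annotation(gt, perfect, 3), gt)

  misser <- annotator_spec("m", miss_probability = 1)
  for (s in 1:5)
    expect_true(is_no_finding(simulate_annotation(gt, misser, s)))

  # jittered annotations stay near the truth; spammers do not track it
  noisy <- annotator_spec("n", boundary_jitter = 2, pixel_noise = 0.05,
                          miss_probability = 0)
  spam <- annotator_spec("s", spammer = TRUE)
  noisy_iou <- vapply(1:50, function(s)
    mask_iou(simulate_annotation(gt, noisy, s), gt), numeric(1))
  spam_iou <- vapply(1:50, function(s)
    mask_iou(simulate_annotation(gt, spam, s), gt), numeric(1))
  expect_gt(mean(noisy_iou), 0.5)
  expect_gt(mean(noisy_iou), mean(spam_iou) + 0.2)
  # determinism per seed
  expect_identical(simulate_annotation(gt, noisy, 7),
                   simulate_annotation(gt, noisy, 7))
})

test_that("simulate_pool streams are hierarchically seeded and stable", {
  scene <- scene_spec(width = 24, height = 24)
  specs <- default_pool_specs(3, 1, 1)
  pool <- simulate_pool(specs, scene, 11)
  gt <- pool$ground_truth(1)

  a1 <- pool$annotate("good_01", "frame_1", "bowel", gt$bowel)
  expect_identical(a1, pool$annotate("good_01", "frame_1", "bowel", gt$bowel))

  # adding an annotator does not perturb existing streams
  pool2 <- simulate_pool(c(specs, list(annotator_spec("extra"))), scene, 11)
  expect_identical(pool2$annotate("good_01", "frame_1", "bowel", gt$bowel), a1)
  expect_identical(pool2$ground_truth(1), gt)

  expect_error(pool$annotate("nobody", "f", "bowel", gt$bowel), "unknown annotator")
  expect_error(simulate_pool(c(specs, specs), scene, 1), "duplicate")
})

test_that("perfect pools reproduce ground truth with zero difficulty", {
  cfg <- campaign_config(seed = 2)
  pool <- perfect_pool(5, scene_spec(width = 16, height = 16), seed = 2)
  res <- run_campaign(10, pool, cfg)
  expect_equal(res$ledger$pending_tasks, 0)
  for (key in names(res$consensus)) {
    rec <- res$consensus[[key]]
    expect_identical(unclass(rec$mask),
                     unclass(res$ground_truth[[rec$frame_id]][[rec$structure]]))
  }
  expect_true(all(vapply(res$difficulty, `[[`, numeric(1), "di") == 0))
})

test_that("a lone spammer cannot defeat a 4-of-5 majority of perfect annotators", {
  specs <- c(lapply(1:4, function(i)
    annotator_spec(sprintf("perfect_%d", i), boundary_jitter = 0,
                   pixel_noise = 0, miss_probability = 0)),
    list(annotator_spec("spam", spammer = TRUE)))
  scene <- scene_spec(width = 16, height = 16,
                      structures = list(bowel = list(
                        presence_probability = 0.8, blob_count = c(1, 2),
                        blob_radius = c(3, 6))))
  pool <- simulate_pool(specs, scene, 4)
  cfg <- campaign_config(structures = list(bowel = list(n_min = 5, mv = 4)),
                         ts_min = 0, rs_min = 0, seed = 4)  # let the spammer in
  res <- run_campaign(10, pool, cfg)
  for (rec in res$consensus) {
    expect_equal(rec$status, "complete")
    expect_identical(unclass(rec$mask),
                     unclass(res$ground_truth[[rec$frame_id]]$bowel))
  }
})
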