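mk_gold <- function(k, h = 8, w = 8) {
  # k visible gold tasks with distinct frames, plus matching references
  lapply(seq_len(k), function(i) {
    mask <- mask_from_coords(h, w, rbind(c(2, 2), c(2, 3), c(3, 2), c(3, 3)))
    base::structure(list(frame_id = sprintf("g%02d", i), structure = "bowel",
                         expert_id = "e1", mask = mask),
                    class = "expert_reference")
  })
}

gold_annotation <- function(ref, aid, mask, role = "training_gold")
  annotation(aid, ref$frame_id, ref$structure, mask, role = role)

test_that("score_training averages per-task IoU and gates on ts_min", {
  cfg <- campaign_config(n_training_gold = 10)
  refs <- mk_gold(10)
  perfect <- lapply(refs, function(r) gold_annotation(r, "a", r$mask))
  disjoint_mask <- mask_from_coords(8, 8, rbind(c(6, 6)))
  disjoint <- lapply(refs, function(r) gold_annotation(r, "a", disjoint_mask))

  p <- score_training(annotator_profile("a"), perfect, refs, cfg)
  expect_equal(p$ts, 1)
  expect_true(p$qualified)
  expect_length(p$training_scores, 10)

  p0 <- score_training(annotator_profile("a"), disjoint, refs, cfg)
  expect_equal(p0$ts, 0)
  expect_false(p0$qualified)

  mixed <- c(perfect[1:5], disjoint[6:10])
  pm <- score_training(annotator_profile("a"), mixed, refs, cfg)
  expect_equal(pm$ts, 0.5)

  expect_error(score_training(annotator_profile("a"), perfect[1:9], refs, cfg),
               "exactly 10")
  # missing reference is a configuration error
  stray <- c(perfect[1:9], list(annotation("a", "unknown", "bowel",
                                           refs[[1]]$mask,
                                           role = "training_gold")))
  expect_error(score_training(annotator_profile("a"), stray, refs, cfg),
               "no expert reference")
})

test_that("running score is a rolling mean over the window", {
  cfg <- campaign_config(rs_window = 3)
  refs <- mk_gold(4)
  p <- score_training(annotator_profile("a"),
                      lapply(mk_gold(10), function(r)
                        gold_annotation(r, "a", r$mask)),
                      mk_gold(10), cfg)
  feed <- function(p, ref, mask) {
    update_running_score(p, gold_annotation(ref, "a", mask,
                                            role = "running_gold"), ref, cfg)
  }
  empty <- mask_from_coords(8, 8)

  p1 <- feed(p, refs[[1]], refs[[1]]$mask)
  expect_equal(p1$rs, 1)                       # single-element mean
  p2 <- feed(feed(p1, refs[[2]], refs[[2]]$mask), refs[[3]], refs[[3]]$mask)
  expect_equal(p2$rs, 1)                       # [1,1,1]
  p3 <- feed(p2, refs[[4]], empty)             # IoU 0 enters, oldest 1 drops
  expect_equal(p3$rs, 2 / 3)
  expect_true(p3$qualified)                    # 2/3 still clears rs_min = 0.5
  # two more misses push RS to 1/3 and disqualify prospectively
  p5 <- feed(feed(p3, refs[[1]], empty), refs[[2]], refs[[2]]$mask)
  expect_equal(p5$rs, 1 / 3)
  expect_false(p5$qualified)
})

test_that("qualification is the conjunction of the TS and RS gates", {
  cfg <- campaign_config(ts_min = 0.5, rs_min = 0.5)
  p <- annotator_profile("a")
  expect_error(is_qualified(p, cfg), "no training score")

  p$ts <- 1.0
  expect_true(is_qualified(p, cfg))            # no running tests yet
  p$ts <- 0.4
  expect_false(is_qualified(p, cfg))           # TS gate fails regardless of RS
  p$rs <- 1.0
  expect_false(is_qualified(p, cfg))
  p$ts <- 0.9; p$rs <- 0.3
  expect_false(is_qualified(p, cfg))           # RS gate fails
  p$rs <- 0.5
  expect_true(is_qualified(p, cfg))

  # gate monotonicity: raising a threshold never qualifies anyone new
  with_seed(5, {
    for (i in 1:50) {
      p$ts <- runif(1); p$rs <- runif(1)
      t1 <- runif(1); t2 <- runif(1, t1, 1)
      q_low <- is_qualified(p, campaign_config(ts_min = t1, rs_min = t1))
      q_high <- is_qualified(p, campaign_config(ts_min = t2, rs_min = t2))
      expect_true(q_low || !q_high)
    }
  })
})

test_that("interleave_gold inserts gold at the expected rate, reproducibly", {
  tasks <- sprintf("t%04d", 1:1000)
  s1 <- interleave_gold(tasks, c("g1", "g2"), cadence = 10, seed = 99)
  s2 <- interleave_gold(tasks, c("g1", "g2"), cadence = 10, seed = 99)
  expect_identical(s1, s2)                     # determinism under the seed
  n_gold <- sum(s1$role == "running_gold")
  expect_lt(abs(n_gold - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_true(all(s1$task[s1$role == "running_gold"] %in% c("g1", "g2")))
  expect_equal(s1$task[s1$role == "ordinary"], tasks)  # order preserved

  every <- interleave_gold(sprintf("t%d", 1:50), "g1", cadence = 1, seed = 1)
  expect_equal(sum(every$role == "running_gold"), 50)  # cadence 1: gold after each

  expect_error(interleave_gold(tasks, character(0), 10, 1), "empty")
  expect_error(interleave_gold(tasks, "g1", 0, 1), "cadence")
})

test_that("spammers fail training against non-trivial gold references", {
  cfg <- campaign_config(n_training_gold = 10)
  scene <- scene_spec(width = 24, height = 24,
                      structures = list(bowel = list(
                        presence_probability = 1, blob_count = c(1, 2),
                        blob_radius = c(4, 8))))
  n_low <- 0
  for (seed in 1:200) {
    refs <- lapply(1:10, function(i) {
      gt <- make_ground_truth(scene, i, seed)$bowel
      base::structure(list(frame_id = sprintf("g%02d", i), structure = "bowel",
                           expert_id = "e", mask = gt),
                      class = "expert_reference")
    })
    spam <- annotator_spec("spam", spammer = TRUE)
    anns <- lapply(refs, function(r)
      annotation("spam", r$frame_id, "bowel",
                 simulate_annotation(r$mask, spam,
                                     derive_seed(seed, "sp", r$frame_id)),
                 role = "training_gold"))
    p <- score_training(annotator_profile("spam"), anns, refs, cfg)
    if (p$ts < 0.3) n_low <- n_low + 1
    expect_false(p$qualified)  # default gate excludes the spammer every time
  }
  expect_gte(n_low / 200, 0.99)
})
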