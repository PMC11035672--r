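test_that("mask construction and coordinate convention", {
  m <- mask_from_coords(4, 4, rbind(c(0, 1), c(2, 3)))
  expect_s3_class(m, "binary_mask")
  expect_equal(sum(m), 2)
  # 0-based (row, col): row 0 col 1 is matrix element [1, 2]
  expect_true(unclass(m)[1, 2])
  expect_true(unclass(m)[3, 4])
  expect_equal(mask_coords(m), cbind(row = c(0L, 2L), col = c(1L, 3L)))

  expect_true(is_no_finding(mask_from_coords(4, 4)))
  expect_error(mask_from_coords(4, 4, rbind(c(4, 0))), "out of bounds")
  expect_error(binary_mask(matrix(NA, 2, 2)), "NA")
})

test_that("read_mask binarizes at the 128 threshold and rejects bad input", {
  tmp <- withr::local_tempdir()
  # all-zero and saturated images
  png::writePNG(matrix(0, 4, 4), file.path(tmp, "zero.png"))
  expect_true(is_no_finding(read_mask(file.path(tmp, "zero.png"))))
  png::writePNG(matrix(1, 4, 4), file.path(tmp, "one.png"))
  expect_equal(sum(read_mask(file.path(tmp, "one.png"))), 16)
  # pixels exactly (0,1) and (2,3) set, written independently of write_mask
  img <- matrix(0, 4, 4); img[1, 2] <- 1; img[3, 4] <- 1
  png::writePNG(img, file.path(tmp, "two.png"))
  expect_equal(mask_coords(read_mask(file.path(tmp, "two.png"))),
               cbind(row = c(0L, 2L), col = c(1L, 3L)))
  # grey levels straddling the threshold: 127 -> background, 128 -> fg
  png::writePNG(matrix(c(127, 128, 0, 255) / 255, 2, 2), file.path(tmp, "grey.png"))
  expect_equal(sum(read_mask(file.path(tmp, "grey.png"))), 2)
  # multi-channel is a format error naming the file
  png::writePNG(array(0.5, c(2, 2, 3)), file.path(tmp, "rgb.png"))
  expect_error(read_mask(file.path(tmp, "rgb.png")), "rgb.png")
  expect_error(read_mask(file.path(tmp, "nope.png")), "no such file")
})

test_that("write/read round trip is the identity", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "m.png")
  roundtrip <- function(m) { write_mask(m, p); read_mask(p) }

  expect_equal(roundtrip(mask_from_coords(5, 7)), mask_from_coords(5, 7))
  one <- mask_from_coords(5, 7, rbind(c(2, 3)))
  expect_equal(roundtrip(one), one)
  for (seed in 1:10) {
    m <- with_seed(seed, random_mask(64, 64, p = runif(1)))
    expect_equal(roundtrip(m), m)
  }
  expect_error(write_mask(one, file.path(tmp, "absent", "m.png")),
               "no such directory")
})

test_that("manifest loading validates schema, keys and paths", {
  tmp <- withr::local_tempdir()
  dir.create(file.path(tmp, "masks"))
  write_mask(mask_from_coords(4, 4, rbind(c(1, 1))), file.path(tmp, "masks", "a.png"))
  write_mask(mask_from_coords(4, 4), file.path(tmp, "masks", "b.png"))

  hdr <- "annotator_id,frame_id,structure,role,mask_path,elapsed_s"
  man <- file.path(tmp, "manifest.csv")

  writeLines(hdr, man)
  expect_length(load_manifest(man), 0)

  writeLines(c(hdr,
               "w1,f1,bowel,ordinary,masks/a.png,12.5",
               "w2,f1,bowel,training_gold,masks/b.png,"), man)
  anns <- load_manifest(man)
  expect_length(anns, 2)
  expect_equal(anns[[1]]$annotator_id, "w1")
  expect_equal(anns[[1]]$elapsed_s, 12.5)
  expect_equal(sum(anns[[1]]$mask), 1)
  expect_equal(anns[[2]]$role, "training_gold")
  expect_true(is_no_finding(anns[[2]]$mask))

  # loading is order-independent up to record order by key
  writeLines(c(hdr,
               "w2,f1,bowel,training_gold,masks/b.png,",
               "w1,f1,bowel,ordinary,masks/a.png,12.5"), man)
  anns2 <- load_manifest(man)
  key <- function(x) vapply(x, function(a)
    paste(a$annotator_id, a$frame_id, a$structure), character(1))
  expect_setequal(key(anns2), key(anns))

  writeLines(c(hdr,
               "w1,f1,bowel,ordinary,masks/a.png,1",
               "w1,f1,bowel,ordinary,masks/b.png,2"), man)
  expect_error(load_manifest(man), "duplicate")

  writeLines(c(hdr, "w1,f1,bowel,ordinary,masks/missing.png,1"), man)
  expect_error(load_manifest(man), "missing.png")

  writeLines(c("annotator_id,frame_id,structure", "w1,f1,bowel"), man)
  expect_error(load_manifest(man), "missing column")

  writeLines(c(hdr, "w1,f1,bowel,supervisor,masks/a.png,1"), man)
  expect_error(load_manifest(man), "unknown role")
})

test_that("expert reference table enforces its uniqueness invariant", {
  tmp <- withr::local_tempdir()
  write_mask(mask_from_coords(4, 4, rbind(c(1, 1))), file.path(tmp, "r.png"))
  refs <- file.path(tmp, "experts.csv")
  writeLines(c("frame_id,structure,expert_id,mask_path",
               "f1,bowel,e1,r.png", "f1,bowel,e2,r.png"), refs)
  expect_length(load_expert_refs(refs), 2)
  writeLines(c("frame_id,structure,expert_id,mask_path",
               "f1,bowel,e1,r.png", "f1,bowel,e1,r.png"), refs)
  expect_error(load_expert_refs(refs), "duplicate")
})
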