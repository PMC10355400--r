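# Patch extraction geometry, the p >= 0.1 filter, background zeroing,
# synthetic labeling and split inheritance.

.const_image <- function(H, W, id = "imA", value = 0.5) {
  ImageRecord(id, "2018-01-05 10:00:00",
              array(value, c(H, W, 3)), "K0", "theta1")
}

test_that("patch extraction follows the bounding-box grid and the filter", {
  img <- .const_image(300, 300)
  lab <- matrix(0L, 300, 300)
  expect_identical(nrow(patchInfo(extractPatches(img, LabelMask(lab)))), 0L)

  # a full 128 x 128 block: p = 1, single tile at the block origin
  lab2 <- matrix(0L, 300, 300)
  lab2[21:148, 31:158] <- 1L
  ps <- extractPatches(img, LabelMask(lab2), "C_r")
  expect_identical(nrow(patchInfo(ps)), 1L)
  expect_identical(patchInfo(ps)$p, 1)
  expect_identical(patchInfo(ps)$x, 30L)
  expect_identical(patchInfo(ps)$y, 20L)

  # 1638 coral pixels in the tile: p = 1638/16384 < 0.1, discarded
  lab3 <- matrix(0L, 300, 300)
  lab3[1:18, 1:91] <- 1L                       # 18 * 91 = 1638
  expect_identical(nrow(patchInfo(extractPatches(img, LabelMask(lab3)))), 0L)
  lab3[18, 92] <- 1L                           # 1639 pixels: kept
  ps3 <- extractPatches(img, LabelMask(lab3))
  expect_identical(nrow(patchInfo(ps3)), 1L)
  expect_equal(patchInfo(ps3)$p, 1639 / 16384)

  expect_error(extractPatches(.const_image(10, 10), LabelMask(lab2)),
               "sizes differ")
})

test_that("stored p matches brute-force pixel counting; background is zeroed", {
  set.seed(21)
  for (rep in 1:20) {
    H <- 260; W <- 300
    img <- .const_image(H, W, value = 0.7)
    lab <- matrix(0L, H, W)
    y <- sample(1:(H - 60), 1); x <- sample(1:(W - 60), 1)
    lab[y:min(H, y + sample(40:160, 1)), x:min(W, x + sample(40:160, 1))] <- 1L
    ones <- which(lab == 1L)
    lab[sample(ones, length(ones) %/% 3)] <- 0L   # ragged interior
    ps <- extractPatches(img, LabelMask(lab), "C_r")
    info <- patchInfo(ps)
    for (i in seq_len(nrow(info))) {
      rows <- (info$y[i] + 1):min(info$y[i] + 128, H)
      cols <- (info$x[i] + 1):min(info$x[i] + 128, W)
      expect_identical(info$p[i], sum(lab[rows, cols] == 1L) / (128 * 128))
      tile <- patchPixels(ps)[[i]]
      inside <- lab[rows, cols] == 1L
      sub <- tile[seq_along(rows), seq_along(cols), 1]
      expect_true(all(sub[!inside] == 0))
      expect_true(all(sub[inside] > 0))
    }
    # tiles never overlap and jointly cover every coral pixel
    if (nrow(info) > 1) {
      expect_false(any(duplicated(info[, c("x", "y")])))
      expect_true(all(diff(sort(unique(info$x))) %% 128 == 0))
    }
  }
})

test_that("synthetic state labeling implements the 20% rule with the filter", {
  ps <- mk_patchset(p = c(0.5, 0.5))
  states <- data.frame(
    coral = "C_r",
    cell_x = c(8, 9, 10, 11, 12), cell_y = 0,
    extended = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # patch 1 covers x in [8, 16) (cell_size 1): 5 cells inside, 2/5 extended
  lab <- labelPatchesFromStates(patchSubset(ps, 1), states, cell_size = 1L)
  expect_identical(patchInfo(lab)$k, 1L)       # 40% > 20%
  states$extended <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  lab2 <- labelPatchesFromStates(patchSubset(ps, 1), states, cell_size = 1L)
  expect_identical(patchInfo(lab2)$k, 0L)      # 20% is not > 20%
})

test_that("label ingestion validates ids and classes", {
  ps <- mk_patchset(p = c(0.5, 0.3))
  tab <- data.frame(patch_id = patchInfo(ps)$patch_id, k = c(1L, 0L))
  out <- ingestPatchLabels(ps, tab)
  expect_identical(patchInfo(out)$k, c(1L, 0L))
  expect_error(ingestPatchLabels(ps, data.frame(patch_id = "ghost", k = 1L)),
               "filtered or unknown")
  expect_error(ingestPatchLabels(ps, data.frame(patch_id = tab$patch_id[1],
                                                k = 2L)), "0 or 1")
})

test_that("patches inherit their image's split and splits never overlap", {
  scenes <- lapply(1:6, function(i) tiny_scene(i))
  ids <- vapply(scenes, function(s) s$image@image_id, "")
  split <- list(train = ids[1:3], val = ids[4:5], test = ids[6])
  ds <- buildPatchDatasets(scenes, split, "C_r")
  for (nm in names(ds)) {
    got <- unique(patchInfo(ds[[nm]])$image_id)
    expect_true(all(got %in% split[[nm]]))
  }
  inter <- intersect(patchInfo(ds$train)$image_id,
                     c(patchInfo(ds$val)$image_id,
                       patchInfo(ds$test)$image_id))
  expect_length(inter, 0L)
  bad <- list(train = ids[1:3], val = ids[3:4], test = ids[5:6])
  expect_error(buildPatchDatasets(scenes, bad, "C_r"), "more than one split")
})

test_that("combined datasets have additive sizes for disjoint inputs", {
  a <- mk_patchset(p = c(0.5, 0.6), image_id = "imA")
  b <- mk_patchset(p = 0.4, image_id = "imB")
  expect_identical(nrow(patchInfo(combinePatchSets(a, b))), 3L)
})
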