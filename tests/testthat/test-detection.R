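# Region extraction, the barycenter split and the full detect pipeline.

test_that("regions carry exact areas, barycenters and tight boxes", {
  expect_identical(extract_regions(matrix(0L, 8, 8)), list())

  m <- matrix(0L, 20, 20)
  m[5:14, 5:14] <- 1L
  regs <- extract_regions(m)
  expect_length(regs, 1)
  r <- regs[[1]]
  expect_equal(r$area, 100)
  expect_equal(unname(r$centroid), c(9.5, 9.5))
  expect_equal(unname(r$bbox), c(5, 5, 10, 10))

  m2 <- matrix(0L, 20, 30)
  m2[3:6, 20:23] <- 1L    # appears later in row-major order
  m2[10:13, 2:5] <- 1L
  regs2 <- extract_regions(m2)
  expect_length(regs2, 2)
  expect_equal(unname(regs2[[1]]$bbox[1:2]), c(3, 20))
  expect_equal(unname(regs2[[2]]$bbox[1:2]), c(10, 2))
  expect_equal(vapply(regs2, `[[`, integer(1), "id"), 1:2)
})

test_that("the adjoining-pair flag is a strict width/height ratio test", {
  mk <- function(h, w) {
    m <- matrix(0L, h + 4L, w + 4L); m[3:(2L + h), 3:(2L + w)] <- 1L
    extract_regions(m)[[1]]
  }
  expect_true(is_adjoining_pair(mk(50, 100), 1.4))
  expect_false(is_adjoining_pair(mk(100, 50), 1.4))
  expect_false(is_adjoining_pair(mk(50, 70), 1.4))   # exactly 1.4: not >
})

test_that("barycenter split partitions a dumbbell into its two lobes", {
  m <- dumbbell_mask(side = 20L, bridge = 8L)
  r <- extract_regions(m)[[1]]
  parts <- split_at_barycenter(r)
  # partition contract: union is the region, intersection empty
  key <- function(px) paste(px[, 1], px[, 2])
  expect_setequal(c(key(parts[[1]]$pixels), key(parts[[2]]$pixels)),
                  key(r$pixels))
  expect_length(intersect(key(parts[[1]]$pixels), key(parts[[2]]$pixels)), 0)
  # symmetric dumbbell: parts within a bridge-row of equal area
  expect_lte(abs(parts[[1]]$area - parts[[2]]$area), 2)
  # oracle: direct partition at the known centroid column
  cc <- mean(r$pixels[, 2])
  expect_equal(parts[[1]]$area, sum(r$pixels[, 2] < cc))
  expect_equal(parts[[2]]$area, sum(r$pixels[, 2] >= cc))
  # each part's box hugs its own square (the bridge adds a sliver)
  expect_equal(unname(parts[[1]]$bbox[c(1, 2)]), c(6, 6))
  expect_equal(unname(parts[[1]]$bbox[4]), 20 + 4)  # square + half bridge
  # a single-column region cannot be split
  thin <- matrix(0L, 10, 5); thin[2:8, 3] <- 1L
  expect_error(split_at_barycenter(extract_regions(thin)[[1]]), "column")
})

test_that("a perfectly symmetric region splits into equal halves", {
  m <- matrix(0L, 12, 21)
  m[3:10, 4:17] <- 1L   # even width: halves exactly equal
  parts <- split_at_barycenter(extract_regions(m)[[1]])
  expect_equal(parts[[1]]$area, parts[[2]]$area)
})

test_that("detect_clusters finds isolated and adjoining fixtures", {
  fit <- fixture_fit()

  one <- generate_scene(scene_spec(clusters = 1L, seed = 301))
  d1 <- detect_clusters(one$image, fit)
  expect_equal(nrow(d1$boxes), 1L)
  expect_gte(pra(one$mask, d1$mask), 75)

  adj <- generate_scene(scene_spec(adjoining = TRUE, cluster_rx = 26,
                                   cluster_ry = 26, seed = 302))
  expect_equal(max(label_components(adj$mask)), 1L)  # merged in truth
  d2 <- detect_clusters(adj$image, fit)
  expect_equal(nrow(d2$boxes), 2L)
  expect_true(all(d2$boxes$split))

  bgonly <- generate_scene(scene_spec(clusters = 0L, seed = 303))
  d3 <- detect_clusters(bgonly$image, fit)
  expect_equal(nrow(d3$boxes), 0L)
})

test_that("detection rectangles are tight and lie within the image", {
  fit <- fixture_fit()
  scene <- generate_scene(scene_spec(seed = 304))
  det <- detect_clusters(scene$image, fit)
  expect_gte(nrow(det$boxes), 1L)
  for (i in seq_len(nrow(det$boxes))) {
    b <- det$boxes[i, ]
    expect_gte(b$top, 1); expect_gte(b$left, 1)
    expect_lte(b$top + b$height - 1, nrow(det$mask))
    expect_lte(b$left + b$width - 1, ncol(det$mask))
    sub <- det$mask[b$top:(b$top + b$height - 1),
                    b$left:(b$left + b$width - 1), drop = FALSE]
    expect_gte(sum(sub), 1)           # contains foreground
    # tight: every border row/column of the box touches foreground of the
    # region it came from (unsplit boxes only; split boxes share an edge)
    if (!b$split) {
      expect_gte(sum(sub[1, ]), 1); expect_gte(sum(sub[nrow(sub), ]), 1)
      expect_gte(sum(sub[, 1]), 1); expect_gte(sum(sub[, ncol(sub)]), 1)
    }
  }
})

test_that("detection is deterministic for fixed inputs", {
  fit <- fixture_fit()
  scene <- generate_scene(scene_spec(seed = 305))
  d1 <- detect_clusters(scene$image, fit)
  d2 <- detect_clusters(scene$image, fit)
  expect_identical(d1$boxes, d2$boxes)
  expect_identical(d1$mask, d2$mask)
})

test_that("box rasterization and overlay drawing stay in bounds", {
  boxes <- data.frame(top = 2L, left = 3L, height = 4L, width = 5L)
  m <- boxes_to_mask(boxes, c(10, 12))
  expect_equal(sum(m), 20)
  expect_equal(m[2, 3], 1L); expect_equal(m[5, 7], 1L)
  expect_equal(m[6, 8], 0L)
  img <- uniform_image(c(0.5, 0.5, 0.5), 10, 12)
  out <- draw_boxes(img, boxes)
  expect_equal(dim(out), dim(img))
  expect_equal(out[2, 3, ], c(1, 0, 0))
})
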