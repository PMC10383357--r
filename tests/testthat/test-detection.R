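test_that("preprocessing enforces the 512x512 black-and-white contract", {
  # upscale the rendered M to 1024x1024: preprocessing must bring it back
  img <- render_shape_image("M")
  big <- img[rep(seq_len(512), each = 2), rep(seq_len(512), each = 2)]
  pre <- preprocess_image(big)
  expect_identical(dim(pre), c(512L, 512L))
  expect_setequal(unique(as.vector(pre)), c(0, 1))
  expect_gt(sum(pre == 0), 1000)   # strokes survive the downscale

  # non-square compliant input is also brought to 512x512
  rect_img <- matrix(1, 300, 400)
  rect_img[100:110, 50:350] <- 0
  expect_identical(dim(preprocess_image(rect_img)), c(512L, 512L))

  expect_error(preprocess_image(matrix(1, 512, 512)),
               "no shape content", class = "solwrite_validation_error")
  gray <- matrix(seq(0, 1, length.out = 512 * 512), 512, 512)
  expect_error(preprocess_image(gray), class = "solwrite_validation_error")
  colr <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_error(preprocess_image(colr), class = "solwrite_validation_error")
})

test_that("Canny edges trace stroke boundaries", {
  expect_equal(sum(detect_edges(matrix(1, 128, 128))), 0)

  # a single horizontal stroke yields two parallel boundary runs
  img <- matrix(1, 128, 128)
  img[60:63, 20:100] <- 0
  e <- detect_edges(img)
  rows_with_edges <- which(rowSums(e) > 20)
  expect_equal(length(rows_with_edges), 2L)
  expect_true(all(diff(rows_with_edges) >= 3))

  # rectangle: every edge pixel lies within 2 px of the drawn outline
  spec <- stroke_spec("rectangle")
  e <- detect_edges(render_shape_image(spec))
  idx <- which(e, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  dmin <- rep(Inf, length(x))
  for (k in seq_len(nrow(spec)))
    dmin <- pmin(dmin, point_segment_distance(spec[k, ], x, y))
  expect_lte(max(dmin), 2 + attr(spec, "stroke_width") / 2)
})

test_that("probabilistic Hough over-detects but is seed-deterministic", {
  e <- detect_edges(render_shape_image("M"))
  raw <- extract_raw_segments(e, seed = 0)
  expect_gte(nrow(raw), 4)
  raw2 <- extract_raw_segments(e, seed = 0)
  expect_identical(raw, raw2)

  # single straight stroke: every raw segment shares the stroke's angle
  img <- matrix(1, 512, 512)
  img[200:203, 50:450] <- 0
  raw <- extract_raw_segments(detect_edges(img), seed = 0)
  expect_gte(nrow(raw), 1)
  expect_true(all(angle_difference(raw$angle, 0) < 2 * pi / 180))

  expect_error(extract_raw_segments(matrix(FALSE, 64, 64)),
               class = "solwrite_detection_error")
})

test_that("duplicate merging reaches the true stroke count and is idempotent", {
  e <- detect_edges(render_shape_image("M"))
  raw <- extract_raw_segments(e, seed = 0)
  merged <- merge_duplicate_segments(raw)
  expect_equal(nrow(merged), 4L)

  # single segment unchanged
  one <- seg1(0, 0, 100, 0)
  m1 <- merge_duplicate_segments(one)
  expect_equal(nrow(m1), 1L)
  expect_equal(as.numeric(m1[1, c("x0", "y0", "x1", "y1")]), c(0, 0, 100, 0))

  # collinear overlapping segments fuse into their union extent
  two <- rbind(seg1(0, 0, 6, 0), seg1(4, 0, 10, 0))
  m2 <- merge_duplicate_segments(two)
  expect_equal(nrow(m2), 1L)
  expect_equal(as.numeric(m2[1, c("x0", "y0", "x1", "y1")]), c(0, 0, 10, 0),
               tolerance = 1e-9)

  # property: idempotent and never increases the count, on random
  # jitter-duplicated segment sets
  set.seed(71)
  for (i in 1:20) {
    base <- seg1(runif(5, 0, 400), runif(5, 0, 400),
                 runif(5, 100, 512), runif(5, 100, 512))
    dup <- base
    dup$x0 <- dup$x0 + runif(5, -3, 3); dup$y0 <- dup$y0 + runif(5, -3, 3)
    dup$x1 <- dup$x1 + runif(5, -3, 3); dup$y1 <- dup$y1 + runif(5, -3, 3)
    all_seg <- rbind(base, dup)
    m <- merge_duplicate_segments(all_seg)
    expect_lte(nrow(m), nrow(all_seg))
    m_again <- merge_duplicate_segments(m)
    expect_equal(m_again, m)
    # no surviving pair still meets the duplicate criterion
    if (nrow(m) > 1) {
      mx <- (m$x0 + m$x1) / 2; my <- (m$y0 + m$y1) / 2
      for (p in seq_len(nrow(m) - 1)) for (q in (p + 1):nrow(m)) {
        dup_pq <- sqrt((mx[p] - mx[q])^2 + (my[p] - my[q])^2) < 15 &&
          angle_difference(m$angle[p], m$angle[q]) < 5 * pi / 180
        expect_false(dup_pq)
      }
    }
  }
})

test_that("topology distinguishes open traces from closed loops", {
  expect_equal(classify_topology(ground_truth_shape("triangle")$segments), "closed")
  expect_equal(classify_topology(ground_truth_shape("M")$segments), "open")
  expect_equal(classify_topology(seg1(0, 0, 100, 100)), "open")
  disconnected <- rbind(seg1(0, 0, 100, 0), seg1(0, 200, 100, 200))
  expect_error(classify_topology(disconnected),
               "single connected", class = "solwrite_detection_error")
})

test_that("start/end assignment follows the bottom-left / bottom-right rule", {
  m <- ground_truth_shape("M")
  expect_equal(m$start, c(80, 432))
  expect_equal(m$end, c(432, 432))

  rect <- ground_truth_shape("rectangle")
  expect_equal(rect$start, rect$end)
  expect_equal(rect$start, c(106, 356))

  # vertical single segment: bottom endpoint starts the trace
  ep <- assign_endpoints(seg1(5, 0, 5, 100))
  expect_equal(ep$start, c(5, 100))
  expect_equal(ep$end, c(5, 0))

  # a T-junction is not a single path
  tee <- rbind(seg1(0, 0, 100, 0), seg1(100, 0, 200, 0), seg1(100, 0, 100, 100))
  expect_error(assign_endpoints(tee, topology = "open"),
               "single path", class = "solwrite_detection_error")
})

test_that("the full pipeline recovers ground truth for every built-in fixture", {
  truth_counts <- c(M = 4L, rectangle = 4L, Pi = 3L, triangle = 3L)
  truth_topo <- c(M = "open", rectangle = "closed", Pi = "open",
                  triangle = "closed")
  for (nm in builtin_shapes()) {
    det <- detected_shape(nm)
    gt <- ground_truth_shape(nm)
    expect_equal(nrow(det$segments), truth_counts[[nm]], label = nm)
    expect_equal(det$topology, truth_topo[[nm]], label = nm)
    expect_equal(det$perimeter, gt$perimeter, tolerance = 0.02, label = nm)
    # each recovered segment lies within 3 px of its ground-truth stroke
    for (k in seq_len(nrow(gt$segments))) {
      h <- vapply(seq_len(nrow(det$segments)), function(j)
        segment_hausdorff(gt$segments[k, ], det$segments[j, ]), numeric(1))
      expect_lte(min(h), 3)
    }
    expect_lte(sqrt(sum((det$start - gt$start)^2)), 3)
    expect_lte(sqrt(sum((det$end - gt$end)^2)), 3)
  }
})

test_that("detection is bit-identical for a fixed seed", {
  img <- render_shape_image("Pi")
  a <- build_shape(img, seed = 7)
  b <- build_shape(img, seed = 7)
  expect_identical(a$segments, b$segments)
  expect_identical(a$start, b$start)
})

test_that("stage failures carry the failing stage's name", {
  err <- tryCatch(build_shape(matrix(1, 512, 512)), error = identity)
  expect_match(conditionMessage(err), "\\[preprocess\\]")
})
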