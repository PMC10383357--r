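test_that("segment angle is orientation-free and handles verticals", {
  expect_equal(segment_angle(seg1(0, 0, 10, 0)), 0)
  expect_equal(segment_angle(seg1(3, 3, 3, 9)), pi / 2)
  expect_equal(segment_angle(seg1(0, 0, 5, 5)), pi / 4)
  # reversing the endpoints leaves the angle unchanged
  set.seed(11)
  for (i in 1:50) {
    s <- seg1(runif(1, 0, 512), runif(1, 0, 512),
              runif(1, 0, 512), runif(1, 0, 512))
    r <- seg1(s$x1, s$y1, s$x0, s$y0)
    expect_equal(angle_difference(segment_angle(s), segment_angle(r)), 0,
                 tolerance = 1e-9)
  }
  expect_error(segment_angle(seg1(2, 2, 2, 2)),
               class = "solwrite_degenerate_segment")
})

test_that("projection parameter is 0 at start, 1 at end, linear beyond", {
  s <- seg1(0, 0, 10, 0)
  expect_equal(projection_parameter(s, 5, 7), 0.5)
  expect_equal(projection_parameter(s, -2, 0), -0.2)
  expect_equal(projection_parameter(s, 13, 4), 1.3)
  expect_equal(projection_parameter(s, 0, 3), 0)
  expect_equal(projection_parameter(s, 10, -2), 1)
  expect_error(projection_parameter(seg1(1, 1, 1, 1), 0, 0),
               class = "solwrite_degenerate_segment")
})

test_that("point-segment distance matches a dense sampling oracle", {
  s <- seg1(0, 0, 10, 0)
  expect_equal(point_segment_distance(s, 5, 3), 3)
  expect_equal(point_segment_distance(s, 12, 0), 2)   # clamped to endpoint
  expect_equal(point_segment_distance(s, 4, 0), 0)    # on the segment
  set.seed(21)
  for (i in 1:200) {
    s <- seg1(runif(1, 0, 512), runif(1, 0, 512),
              runif(1, 0, 512), runif(1, 0, 512))
    x <- runif(1, -50, 562); y <- runif(1, -50, 562)
    expect_equal(point_segment_distance(s, x, y),
                 sampled_segment_distance(s, x, y, n = 1e4),
                 tolerance = 1e-2)
  }
})

test_that("signed line distance has mirror antisymmetry and carrier magnitude", {
  s <- seg1(0, 0, 10, 0)
  expect_equal(signed_line_distance(s, 5, 0), 0)
  d1 <- signed_line_distance(s, 5, 3)
  d2 <- signed_line_distance(s, 5, -3)
  expect_equal(abs(d1), 3)
  expect_equal(d1, -d2)
  set.seed(31)
  for (i in 1:100) {
    s <- seg1(runif(1, 0, 512), runif(1, 0, 512),
              runif(1, 0, 512), runif(1, 0, 512))
    x <- runif(1, 0, 512); y <- runif(1, 0, 512)
    sd <- signed_line_distance(s, x, y)
    t <- projection_parameter(s, x, y)
    ps <- point_segment_distance(s, x, y)
    # segment distance >= carrier-line distance, equal iff the foot of the
    # perpendicular lies between the endpoints
    expect_gte(ps + 1e-9, abs(sd))
    if (t >= 0 && t <= 1) expect_equal(ps, abs(sd), tolerance = 1e-9)
    else expect_gt(ps, abs(sd))
    # reversing the segment negates the sign, keeps the magnitude
    r <- seg1(s$x1, s$y1, s$x0, s$y0)
    expect_equal(signed_line_distance(r, x, y), -sd, tolerance = 1e-9)
    expect_equal(point_segment_distance(r, x, y), ps, tolerance = 1e-9)
  }
})

test_that("all distances are translation invariant", {
  set.seed(41)
  for (i in 1:50) {
    s <- seg1(runif(1, 0, 512), runif(1, 0, 512),
              runif(1, 0, 512), runif(1, 0, 512))
    x <- runif(1, 0, 512); y <- runif(1, 0, 512)
    ox <- runif(1, -300, 300); oy <- runif(1, -300, 300)
    s2 <- seg1(s$x0 + ox, s$y0 + oy, s$x1 + ox, s$y1 + oy)
    expect_equal(point_segment_distance(s2, x + ox, y + oy),
                 point_segment_distance(s, x, y), tolerance = 1e-6)
    expect_equal(signed_line_distance(s2, x + ox, y + oy),
                 signed_line_distance(s, x, y), tolerance = 1e-6)
    expect_equal(projection_parameter(s2, x + ox, y + oy),
                 projection_parameter(s, x, y), tolerance = 1e-6)
  }
})

test_that("nearest_segment agrees with an exhaustive scan and breaks ties low", {
  segs <- rbind(seg1(0, 0, 10, 0), seg1(0, 10, 10, 10))
  expect_equal(nearest_segment(segs, 0, 1), list(index = 1L, distance = 1))
  # equidistant from both rows: the lower index wins
  expect_equal(nearest_segment(segs, 5, 5)$index, 1L)
  set.seed(51)
  segs <- seg1(runif(50, 0, 512), runif(50, 0, 512),
               runif(50, 0, 512), runif(50, 0, 512))
  for (i in 1:40) {
    x <- runif(1, 0, 512); y <- runif(1, 0, 512)
    d <- vapply(seq_len(nrow(segs)), function(k)
      point_segment_distance(segs[k, ], x, y), numeric(1))
    ns <- nearest_segment(segs, x, y)
    expect_equal(ns$index, which.min(d))
    expect_equal(ns$distance, min(d))
  }
  expect_error(nearest_segment(segs[0, ], 1, 1),
               class = "solwrite_validation_error")
})

test_that("draw-point legality equals min-distance <= radius", {
  rect <- ground_truth_shape("rectangle")
  on_line <- is_legal_draw_point(rect, 200, 156, radius = 20)
  expect_true(on_line$legal)
  expect_equal(on_line$deviation, 0)
  # 25 px away from every segment is illegal at the strictest radius, 20 px
  far <- is_legal_draw_point(rect, 256, 156 + 25, radius = 20)
  expect_false(far$legal)
  expect_equal(abs(far$deviation), 25)
  set.seed(61)
  for (i in 1:1000) {
    x <- runif(1, 0, 512); y <- runif(1, 0, 512)
    d <- min(vapply(seq_len(nrow(rect$segments)), function(k)
      point_segment_distance(rect$segments[k, ], x, y), numeric(1)))
    expect_equal(is_legal_draw_point(rect, x, y, 20)$legal, d <= 20)
  }
})
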