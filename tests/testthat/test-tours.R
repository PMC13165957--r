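test_that("tour length implements the closed/open objective", {
  tri <- data.frame(x = c(0, 3, 0), y = c(0, 0, 4))
  expect_equal(tour_length(tri), 12)                  # 3 + 5 + 4
  expect_equal(tour_length(tri, closed = FALSE), 8)   # 3 + 5
  expect_equal(tour_length(data.frame(x = 1, y = 1)), 0)
  expect_error(tour_length(data.frame(x = numeric(0), y = numeric(0))),
               "zero points")
  expect_error(tour_length(tri, order = c(1, 1, 2)), "permutation")
  expect_error(tour_length(tri, order = c(1, 2)), "permutation")
})

test_that("closed length is invariant under rotation and reversal", {
  pts <- random_points(9, seed = 21)
  ord <- sample(9)
  base <- tour_length(pts, ord)
  for (k in 1:8) {
    rot <- c(ord[(k + 1):9], ord[1:k])
    expect_equal(tour_length(pts, rot), base)
  }
  expect_equal(tour_length(pts, rev(ord)), base)
  # open length is not generally invariant, only reversal-symmetric
  expect_equal(tour_length(pts, rev(ord), closed = FALSE),
               tour_length(pts, ord, closed = FALSE))
})

test_that("reciprocating traversal serpentines band by band", {
  sq <- unit_square()
  t <- reciprocating_tour(sq, band_height = 0.5)
  expect_equal(tour_order(t), c(1L, 2L, 4L, 3L)) # L-to-R then R-to-L
  expect_equal(tour_len(t), 4)                   # closed square perimeter

  # collinear row: one band, plain x-sort, open length = x-range
  row <- data.frame(x = c(5, 1, 3), y = c(2, 2, 2))
  tr <- reciprocating_tour(row)
  expect_equal(tour_order(tr), c(2L, 3L, 1L))
  expect_equal(tour_len(tr, closed = FALSE), 4)

  t1 <- reciprocating_tour(data.frame(x = 3, y = 3))
  expect_equal(tour_len(t1), 0)
  expect_error(reciprocating_tour(sq, band_height = -1), "positive")
  expect_error(reciprocating_tour(data.frame(x = numeric(0), y = numeric(0))),
               "empty")
})

test_that("nearest-neighbour construction is greedy with lowest-index ties", {
  chain <- data.frame(x = c(0, 1, 2), y = c(0, 0, 0))
  expect_equal(tour_order(nearest_neighbor_tour(chain, 1)), 1:3)
  # points 2 and 3 equidistant from 1: lower index wins
  tie <- data.frame(x = c(0, 1, -1), y = c(0, 0, 0))
  expect_equal(tour_order(nearest_neighbor_tour(tie, 1))[2], 2L)
  expect_error(nearest_neighbor_tour(chain, 7), "index")
  # n <= 3: any closed tour is optimal; NN must match brute force
  tri <- data.frame(x = c(0, 4, 1), y = c(0, 1, 3))
  expect_equal(tour_len(nearest_neighbor_tour(tri)),
               tour_len(brute_force_optimal(tri)))
})

test_that("2-opt uncrosses tours and never lengthens them", {
  cr <- crossing_square()
  before <- tour_length(cr) # 2 + 2*sqrt(2)
  expect_equal(before, 2 + 2 * sqrt(2))
  expect_equal(tour_crossings(cr, 1:4), 1L)
  t <- two_opt(cr)
  expect_equal(tour_len(t), 4) # brute-force optimum: the perimeter
  expect_equal(tour_len(t), tour_len(brute_force_optimal(cr)))
  expect_equal(tour_crossings(cr, t), 0L)

  # already locally optimal triangle: unchanged
  tri <- data.frame(x = c(0, 3, 0), y = c(0, 0, 4))
  expect_equal(tour_len(two_opt(tri)), 12)
  # n = 2: no move exists
  two <- data.frame(x = c(0, 5), y = c(0, 0))
  expect_equal(tour_order(two_opt(two)), 1:2)
})

test_that("2-opt output is shorter-or-equal and crossing-free on random scenes", {
  for (s in 1:12) {
    pts <- random_points(12, seed = 300 + s)
    start <- withr::with_seed(400 + s, sample(12))
    res <- two_opt(pts, start)
    expect_lte(tour_len(res), tour_length(pts, start) + 1e-9)
    expect_equal(tour_crossings(pts, res), 0L)
  }
})

test_that("brute force enumerates the exact optimum on small instances", {
  expect_equal(tour_len(brute_force_optimal(unit_square())), 4)
  # triangles: every closed order has the same length (the perimeter)
  tri <- data.frame(x = c(0, 2, 5), y = c(1, 4, 0))
  per <- tour_length(tri, c(1, 2, 3))
  expect_equal(tour_len(brute_force_optimal(tri)), per)
  # out-and-back pair
  two <- data.frame(x = c(0, 3), y = c(4, 0))
  expect_equal(tour_len(brute_force_optimal(two)), 10)
  expect_error(brute_force_optimal(data.frame(x = 1, y = 1)), "n")
  expect_error(brute_force_optimal(random_points(10, 1)), "n")
  # oracle is never beaten by any random permutation
  pts <- random_points(7, seed = 77)
  opt <- tour_len(brute_force_optimal(pts))
  for (s in 1:25) {
    expect_gte(tour_length(pts, withr::with_seed(s, sample(7))), opt - 1e-9)
  }
})

test_that("tour objects expose order, lengths and glance", {
  pts <- random_points(6, seed = 5)
  t <- nearest_neighbor_tour(pts)
  expect_s3_class(t, "rose_tour")
  expect_setequal(tour_order(t), 1:6)
  expect_equal(tour_len(t), tour_length(pts, tour_order(t)))
  expect_equal(tour_len(t, closed = FALSE),
               tour_length(pts, tour_order(t), closed = FALSE))
  g <- glance(t)
  expect_equal(g$n, 6)
  expect_equal(g$planner, "nearest_neighbor")
})
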