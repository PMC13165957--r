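test_that("complexity score matches its closed form and limits", {
  expect_equal(complexity_score(0, 0), 0)
  expect_equal(complexity_score(1, 1), 0.5) # 0.6 * 0.5 + 0.4 * 0.5
  expect_lt(complexity_score(1e9, 1e9), 1)  # saturates below 1
  expect_gt(complexity_score(1e9, 1e9), 0.999)
  expect_error(complexity_score(-1, 0), "non-negative")
  # custom weights must still sum to one
  expect_error(gate_config(w_time = 0.7, w_distance = 0.4), "equal 1")
  cfg <- gate_config(w_time = 0.5, w_distance = 0.5)
  expect_equal(complexity_score(1, 0, cfg), 0.25)
})

test_that("complexity score is strictly increasing in each argument", {
  rho <- seq(0, 5, length.out = 25)
  d <- seq(0, 5, length.out = 25)
  along_rho <- complexity_score(rho, 1)
  along_d <- complexity_score(1, d)
  expect_true(all(diff(along_rho) > 0))
  expect_true(all(diff(along_d) > 0))
})

test_that("scene statistics: count, density per reference tile, mean pair distance", {
  st <- scene_stats(data.frame(x = c(0, 3), y = c(0, 4)), 100, 100)
  expect_equal(st$n, 2)
  expect_equal(st$d_bar, 5)                      # single 3-4-5 pair
  expect_equal(st$rho, 2 / 100)                  # default: n per 1% tile
  expect_equal(st$d_norm, 5 / sqrt(2 * 100^2))   # diagonal normalization

  st3 <- scene_stats(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)), 10, 10)
  expect_equal(st3$d_bar, 4 / 3)                 # (1 + 2 + 1) / 3

  st1 <- scene_stats(data.frame(x = 5, y = 5), 10, 10)
  expect_equal(st1$n, 1)
  expect_equal(st1$d_bar, 0)

  # fixed reference tile overrides the fractional default
  stf <- scene_stats(data.frame(x = c(0, 3), y = c(0, 4)), 100, 100,
                     gate_config(density_ref_area = 1000))
  expect_equal(stf$rho, 2 / 10)
  # nearest-neighbour variant
  stnn <- scene_stats(data.frame(x = c(0, 1, 5), y = c(0, 0, 0)), 10, 10,
                      gate_config(pair_method = "nearest_neighbor"))
  expect_equal(stnn$d_bar, mean(c(1, 1, 4)))
})

test_that("planner selection transcribes the decision tree literally", {
  # hard count rules dominate everything else
  expect_equal(select_algorithm(2, 0.99, 0.99, "bud"), "reciprocating")
  expect_equal(select_algorithm(21, 0, 0, "bloom"), "genetic")
  # mid range: score threshold with <= boundary
  expect_equal(select_algorithm(10, 0.40, 0, "bloom"), "reciprocating")
  expect_equal(select_algorithm(10, 0.41, 0, "bloom"), "genetic")
  # bud density override, strict >
  expect_equal(select_algorithm(10, 0.20, 0.6, "bud"), "genetic")
  expect_equal(select_algorithm(10, 0.20, 0.5, "bud"), "reciprocating")
  expect_equal(select_algorithm(10, 0.20, 0.6, "bloom"), "reciprocating")
  # combined tours are not bud tours: no override
  expect_equal(select_algorithm(10, 0.20, 0.9, "combined"), "reciprocating")
  expect_error(select_algorithm(0, 0, 0, "bud"), "empty")
})

test_that("planner selection is a total function over the boundary grid", {
  grid <- expand.grid(n = c(1, 2, 3, 10, 20, 21, 100),
                      c = c(0, 0.39, 0.4, 0.41, 0.99),
                      rho = c(0, 0.49, 0.5, 0.51, 2),
                      category = c("bloom", "bud"),
                      stringsAsFactors = FALSE)
  got <- select_algorithm(grid$n, grid$c, grid$rho, grid$category)
  expect_true(all(got %in% c("reciprocating", "genetic")))
  expect_equal(length(got), nrow(grid))
})

test_that("assess_scene wires stats, score and selection together", {
  sc <- generate_scene(scene_spec(), seed = 5)
  rep_bud <- assess_scene(sc, "bud")
  expect_equal(rep_bud$n, sum(sc$class == "bud"))
  expect_equal(rep_bud$c,
               complexity_score(rep_bud$rho, rep_bud$d_norm))
  expect_equal(rep_bud$selected,
               select_algorithm(rep_bud$n, rep_bud$c, rep_bud$rho, "bud"))
  expect_error(assess_scene(new_scene(data.frame(class = "bloom", x = 1, y = 1),
                                      10, 10), "bud"),
               "no 'bud' waypoints")
})

test_that("a dense bud cluster trips the override under a finer reference tile", {
  # 15 buds packed into a small cluster; with a 1/25-area tile rho = 15/25 > 0.5
  sc <- scene_suite("gate_boundary", count = 6, seed = 3)[[6]]
  cfg <- gate_config(density_ref_frac = 1 / 25)
  rep <- assess_scene(sc, "bud", cfg)
  if (rep$n >= 3 && rep$n <= 20 && rep$rho > 0.5 && rep$c <= 0.4) {
    expect_equal(rep$selected, "genetic")
  }
  expect_equal(rep$selected,
               select_algorithm(rep$n, rep$c, rep$rho, "bud", cfg))
})

test_that("gate configuration round-trips through YAML", {
  cfg <- gate_config(w_time = 0.7, w_distance = 0.3, density_ref_frac = 0.02)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_gate_config(cfg, f)
  back <- read_gate_config(f)
  expect_equal(back, cfg)
})
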