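test_that("xy_direction projects onto XY and flags degenerate segments", {
  mv <- function(x0, y0, z0, x1, y1, z1)
    data.frame(kind = "print", x0 = x0, y0 = y0, z0 = z0,
               x1 = x1, y1 = y1, z1 = z1)
  d <- xy_direction(mv(0, 0, 0, 5, 0, 0))
  expect_equal(c(d$vx, d$vy), c(1, 0))
  expect_equal(d$theta, 0)
  expect_true(xy_direction(mv(0, 0, 0, 0, 0, 0.2))$degenerate)
  d <- xy_direction(mv(0, 0, 0, 3, 3, 1))   # Z ignored
  expect_equal(d$theta, 45)
  expect_equal(sqrt(d$vx^2 + d$vy^2), 1, tolerance = 1e-12)
  expect_error(xy_direction(data.frame(kind = "travel", x0 = 0, y0 = 0,
                                       z0 = 0, x1 = 1, y1 = 0, z1 = 0)),
               "print moves")
})

test_that("classify_sector agrees with the nearest-centre oracle", {
  # all integer degrees, including wraparound and exact boundaries
  theta <- 0:359
  expect_equal(classify_sector(theta), oracle_sector(theta))
  expect_equal(classify_sector(0), 0L)
  expect_equal(classify_sector(30), 1L)
  expect_equal(classify_sector(350), 0L)
  # half-open boundary: 22.5 opens sector 1, 337.5 opens sector 0
  expect_equal(classify_sector(c(22.5, 337.5, 337.4999)), c(1L, 0L, 7L))
  set.seed(101)
  th <- runif(5000, 0, 360)
  expect_equal(classify_sector(th), oracle_sector(th))
})

test_that("sector_to_leds activates the couple(s) opposite the motion", {
  expect_equal(sector_to_leds(0), list(azimuths = 180, n_couples = 1L, code = 1L))
  expect_equal(sector_to_leds(1)$azimuths, c(180, 270))
  expect_equal(sector_to_leds(1)$code, 2L)
  expect_equal(sector_to_leds(4), list(azimuths = 0, n_couples = 1L, code = 5L))
  for (k in 0:7) {
    leds <- sector_to_leds(k)
    expect_equal(leds$code, k + 1L)
    expect_equal(leds$n_couples, if (k %% 2 == 0) 1L else 2L)
    # opposite-side property at the sector centre direction
    theta <- k * 45
    expect_true(all(cos((leds$azimuths - theta) * pi / 180) <=
                      cos(112.5 * pi / 180) + 1e-9))
  }
  expect_error(sector_to_leds(8), "0\\.\\.7")
})

test_that("opposite-side property holds across each whole sector arc", {
  set.seed(11)
  theta <- runif(2000, 0, 360)
  sec <- classify_sector(theta)
  for (i in seq_along(theta)) {
    az <- sector_to_leds(sec[i])$azimuths
    expect_true(all(cos((az - theta[i]) * pi / 180) <=
                      cos(112.5 * pi / 180) + 1e-9))
  }
})

test_that("rotating a path by 45 degrees shifts every code cyclically", {
  rot45 <- function(path) {
    m <- path$moves
    R <- matrix(c(cos(pi / 4), sin(pi / 4), -sin(pi / 4), cos(pi / 4)), 2)
    a <- t(R %*% t(as.matrix(m[, c("x0", "y0")])))
    b <- t(R %*% t(as.matrix(m[, c("x1", "y1")])))
    m[, c("x0", "y0")] <- a; m[, c("x1", "y1")] <- b
    toolpath(m, path$layer_thickness)
  }
  set.seed(202)
  for (rep in 1:150) {
    p <- random_path(n = 5)
    s1 <- schedule_path(p)
    s2 <- schedule_path(rot45(p))
    pr <- p$moves$kind == "print"
    expect_equal(s2$code[pr] - 1L, (s1$code[pr]) %% 8L)
    expect_equal(s2$n_couples[pr] %in% 1:2, rep(TRUE, sum(pr)))
  }
})

test_that("schedule_path covers the serpentine grid as derived by hand", {
  p <- gen_grid_monolayer(20, 20, pitch = 1)
  s <- schedule_path(p)
  expect_equal(s$code, oracle_serpentine_codes(p))
  # rows alternate 1 and 5, connectors 3
  rows <- s$code[p$moves$kind == "print" & abs(p$moves$y1 - p$moves$y0) < 1e-9]
  expect_equal(unique(rows), c(1L, 5L))
  conns <- s$code[p$moves$kind == "print" & abs(p$moves$x1 - p$moves$x0) < 1e-9]
  expect_equal(unique(conns), 3L)
})

test_that("closed CCW square yields the four cardinal codes in order", {
  p <- toolpath_from_coords(
    data.frame(x = c(10, 10, 0, 0), y = c(0, 10, 10, 0), z = 0.2), feed = 5,
    start = c(0, 0, 0.2))
  s <- schedule_path(p)
  expect_equal(s$code[p$moves$kind == "print"], c(1L, 3L, 5L, 7L))
})

test_that("travel and degenerate segments hold the LED state", {
  m <- data.frame(kind = c("travel", "print", "print", "print"),
                  x0 = c(0, 0, 10, 10), y0 = 0, z0 = c(0, 0.2, 0.2, 0.4),
                  x1 = c(0, 10, 10, 20), y1 = 0, z1 = c(0.2, 0.2, 0.4, 0.4),
                  feed = 5)
  p <- toolpath(m)
  s <- schedule_path(p)
  expect_equal(s$code, c(0L, 1L, 1L, 1L))  # leading travel off, z-hop holds
  expect_true(s$degenerate[3])
  s2 <- schedule_path(p, off_on_travel = TRUE)
  expect_equal(s2$code[1], 0L)
})

test_that("single-move and empty paths schedule sanely", {
  p <- toolpath_from_coords(data.frame(x = 5, y = 0, z = 0), kind = "print",
                            feed = 5, start = c(0, 0, 0))
  s <- schedule_path(p)
  expect_equal(nrow(s), 1L)
  expect_equal(s$code, 1L)
  g <- inject_led_commands(p, s)
  expect_equal(count_m102(g), 1L)
})

test_that("inject_led_commands writes one M102 per code change", {
  p <- gen_grid_monolayer(20, 20, pitch = 1)
  s <- schedule_path(p)
  g <- inject_led_commands(p, s)
  expect_equal(count_m102(g), oracle_m102_count(s$code))
  # M102 dedup invariant: no two consecutive M102 lines with equal codes
  codes <- m102_codes(g)
  expect_true(all(diff(codes) != 0))
  # first print move preceded by an M102 carrying its code
  first_print <- which(grepl("^G1", g))[1]
  prior <- grep("^M102", g[seq_len(first_print)], value = TRUE)
  expect_gt(length(prior), 0)
})

test_that("all-on control mode emits a single M102 P9", {
  p <- gen_grid_monolayer(10, 10, pitch = 2)
  g <- inject_led_commands(p, all_on = TRUE)
  expect_equal(m102_codes(g), 9L)
  expect_equal(count_m102(g), 1L)
})

test_that("trailing_off appends a final all-off command", {
  p <- toolpath_from_coords(data.frame(x = 5, y = 0, z = 0), feed = 5,
                            start = c(0, 0, 0))
  g <- inject_led_commands(p, trailing_off = TRUE)
  expect_equal(m102_codes(g), c(1L, 0L))
  expect_equal(g[length(g)], "M102 P0")
})

test_that("code_to_azimuths inverts the code map and handles extensions", {
  expect_equal(code_to_azimuths(0), numeric(0))
  expect_equal(sort(code_to_azimuths(9)), c(0, 90, 180, 270))
  for (k in 0:7)
    expect_equal(code_to_azimuths(k + 1), sector_to_leds(k)$azimuths)
  expect_error(code_to_azimuths(10), "0\\.\\.9")
})

test_that("a remapped code table is honoured end to end", {
  conv <- sector_convention(code_map = c(8:1))
  expect_equal(sector_to_leds(0, conv)$code, 8L)
  p <- toolpath_from_coords(data.frame(x = 5, y = 0, z = 0), feed = 5,
                            start = c(0, 0, 0))
  s <- schedule_path(p, conv)
  expect_equal(s$code, 8L)
  expect_equal(code_to_azimuths(8, conv), 180)
})
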