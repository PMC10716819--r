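src15 <- function(kappa = 1) source_params(P_L = 60, v_s = 5, distance = 15,
                                           kappa = kappa)

test_that("stationary exposure deposits a uniform in-disk dose, total exact", {
  src <- src15()
  g <- simulate_stationary_exposure(src, duration = 1)
  total <- sum(g$energy) * g$cell^2
  expect_equal(total, attr(g, "emitted_mJ"), tolerance = 1e-12)
  nominal <- src$P_L / (pi * (src$w_0 / 2)^2)   # mW/mm^2 * 1 s
  vals <- g$energy[g$energy > 0]
  expect_equal(length(unique(round(vals, 12))), 1L)  # uniform top-hat
  expect_equal(max(vals), nominal, tolerance = 0.01)
  expect_true(any(g$energy == 0))                    # out-of-disk cells dark
})

test_that("deposited energy is conserved exactly when spots stay in-grid", {
  p <- gen_grid_monolayer(20, 20, pitch = 1)
  s <- schedule_path(p)
  g <- simulate_substrate_exposure(p, s, src15())
  total <- sum(g$energy) * g$cell^2
  emitted <- attr(g, "emitted_mJ")
  expect_lt(abs(total - emitted) / emitted, 1e-6)
  # energy only accumulates: all cells non-negative
  expect_true(all(g$energy >= 0))
})

test_that("light leaving a clipped grid is lost, never gained", {
  p <- gen_grid_monolayer(20, 20, pitch = 1)
  s <- schedule_path(p)
  small <- exposure_grid(c(0, 20), c(0, 20), cell = 0.5)
  expect_error(simulate_substrate_exposure(p, s, src15(), grid = small),
               "grid too small")
  g <- simulate_substrate_exposure(p, s, src15(), grid = small,
                                   allow_clip = TRUE)
  expect_lt(sum(g$energy) * g$cell^2, attr(g, "emitted_mJ"))
})

test_that("grid totals converge under refinement", {
  p <- gen_grid_monolayer(10, 10, pitch = 2)
  s <- schedule_path(p)
  src <- source_params(P_L = 60, v_s = 5, distance = 1)  # small spot
  g1 <- simulate_substrate_exposure(p, s, src,
          grid = auto_exposure_grid(p, src$w_0, cell = 0.5))
  g2 <- simulate_substrate_exposure(p, s, src,
          grid = auto_exposure_grid(p, src$w_0, cell = 0.25))
  t1 <- sum(g1$energy) * g1$cell^2
  t2 <- sum(g2$energy) * g2$cell^2
  expect_lt(abs(t1 - t2) / t2, 0.01)
})

test_that("each serpentine row exposes its trailing side more", {
  # single +x strand across the grid: the active couple sits behind (azimuth
  # 180), so cells behind the strand start accumulate before cells ahead
  p <- toolpath_from_coords(data.frame(x = 20, y = 10, z = 0.2), feed = 5,
                            start = c(0, 10, 0.2))
  p$moves$kind <- "print"
  s <- schedule_path(p)
  src <- source_params(P_L = 60, v_s = 5, distance = 1)
  g <- simulate_substrate_exposure(p, s, src)
  ix_behind <- which.min(abs(g$x - 2))
  ix_ahead <- which.min(abs(g$x - 18))
  iy <- which.min(abs(g$y - 10))
  expect_gt(g$energy[ix_behind, iy], g$energy[ix_ahead, iy] * 0.99)
  # centroid of deposited energy trails the strand midpoint
  cx <- sum(g$energy * g$x) / sum(g$energy)
  expect_lt(cx, 10)
})

test_that("needle energy: directional strictly below the all-on control", {
  src <- src15()
  for (nm in names(fx <- fixture_set())) {
    p <- fx[[nm]]
    dir <- needle_incident_energy(p, schedule_path(p), src)
    ctl <- needle_incident_energy(p, all_on_schedule(p), src)
    expect_gt(ctl$total, dir$total)
    expect_gt(dir$total, 0)
    # totals equal the sum of per-move contributions
    expect_equal(dir$total, sum(dir$contributions$energy))
  }
})

test_that("no active LEDs means zero needle energy", {
  p <- gen_grid_monolayer(10, 10, pitch = 2)
  off <- needle_incident_energy(p, off_schedule(p), src15())
  expect_equal(off$total, 0)
})

test_that("all-on needle dose is four times a single couple's", {
  p <- toolpath_from_coords(data.frame(x = 10, y = 0, z = 0.2), feed = 5,
                            start = c(0, 0, 0.2))
  p$moves$kind <- "print"
  src <- src15()
  one <- needle_incident_energy(p, schedule_path(p), src)   # +x -> 1 couple
  all4 <- needle_incident_energy(p, all_on_schedule(p), src)
  expect_equal(all4$total, 4 * one$total, tolerance = 1e-12)
})

test_that("with the mechanical spot offset the needle sits outside every spot", {
  geom <- led_geometry(spot_offset_mm = 10.6)
  p <- gen_grid_monolayer(10, 10, pitch = 2)
  r <- needle_incident_energy(p, all_on_schedule(p), src15(), geom = geom)
  expect_false(r$needle_in_spot)
  expect_equal(r$total, 0)
})

test_that("compare_schedules reports ratios and degenerate denominators", {
  p <- gen_grid_monolayer(10, 10, pitch = 2)
  s <- schedule_path(p)
  src <- src15()
  self <- compare_schedules(p, s, s, src)
  expect_equal(self$ratio, 1)
  dir_vs_all <- compare_schedules(p, s, all_on_schedule(p), src)
  expect_lt(dir_vs_all$ratio, 1)
  off_vs_all <- compare_schedules(p, off_schedule(p), all_on_schedule(p), src)
  expect_equal(off_vs_all$ratio, 0)
  all_vs_off <- compare_schedules(p, all_on_schedule(p), off_schedule(p), src)
  expect_true(is.infinite(all_vs_off$ratio))
  expect_true(all_vs_off$zero_denominator)
})

test_that("gaussian spot model conserves energy too", {
  p <- toolpath_from_coords(data.frame(x = 10, y = 0, z = 0.2), feed = 5,
                            start = c(0, 0, 0.2))
  p$moves$kind <- "print"
  s <- schedule_path(p)
  g <- simulate_substrate_exposure(p, s, src15(), spot_model = "gaussian")
  total <- sum(g$energy) * g$cell^2
  # gaussian tails extend past the auto grid margin; most energy stays in
  expect_lt(total, attr(g, "emitted_mJ") * (1 + 1e-9))
  expect_gt(total, attr(g, "emitted_mJ") * 0.8)
})

test_that("exposure grid exports as a y-by-x CSV matrix", {
  src <- src15()
  g <- simulate_stationary_exposure(src, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_exposure_csv(g, f)
  d <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(d), length(g$y))
  expect_equal(ncol(d), length(g$x) + 1L)
})
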