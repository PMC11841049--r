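test_that("circle fit is exact on noiseless data", {
  th <- seq(0.1, 2 * pi, length.out = 20)
  fit <- fit_circle(data.frame(x = 10 * cos(th), z = 5 + 10 * sin(th)))
  expect_equal(fit$radius, 10, tolerance = 1e-10)
  expect_equal(unname(fit$center), c(0, 5), tolerance = 1e-10)
})

test_that("three points give their circumcircle", {
  fit <- fit_circle(data.frame(x = c(0, 2, 1), z = c(0, 0, 1)))
  expect_equal(unname(fit$center), c(1, 0), tolerance = 1e-10)
  expect_equal(fit$radius, 1, tolerance = 1e-10)
})

test_that("circle fit is robust to noise and rejects degenerate input", {
  set.seed(99)
  radii <- replicate(50, {
    th <- runif(200, 0, 2 * pi)
    fit_circle(data.frame(x = 10 * cos(th) + rnorm(200, sd = 0.1),
                          z = 10 * sin(th) + rnorm(200, sd = 0.1)))$radius
  })
  expect_equal(mean(radii), 10, tolerance = 0.01)
  expect_error(fit_circle(data.frame(x = 1:5, z = 2 * (1:5))), "collinear")
  expect_error(fit_circle(data.frame(x = 1, z = 1)), "3 points")
})

test_that("contact angle follows the circle geometry and sign convention", {
  mkfit <- function(R, zc) {
    f <- list(radius = R, center = c(x = 0, z = zc), n_points = 10)
    class(f) <- "circle_fit"
    f
  }
  # center on the interface plane: hemicylinder
  expect_equal(contact_angle(mkfit(10, 2), 2)$theta_deg, 90)
  # tangency limits
  expect_equal(contact_angle(mkfit(10, 2 - 10), 2)$theta_deg, 0)
  expect_equal(contact_angle(mkfit(10, 2 + 10), 2)$theta_deg, 180)
  # center 5 above the plane at R = 10: 120 degrees through the droplet
  a <- contact_angle(mkfit(10, 7), 2)
  expect_equal(a$cos_theta, -0.5, tolerance = 1e-12)
  expect_equal(a$theta_deg, 120, tolerance = 1e-10)
  expect_error(contact_angle(mkfit(10, 50), 2), "intersect")
})

test_that("extrapolation in 1/R recovers the macroscopic angle exactly", {
  R <- c(8, 12, 18, 30)
  c0 <- cos(110 * pi / 180)
  d <- data.frame(radius = R, cos_theta = c0 + 2.7 / R)
  ex <- extrapolate_angle(d)
  expect_equal(ex$cos_intercept, c0, tolerance = 1e-12)
  expect_equal(ex$slope, 2.7, tolerance = 1e-10)
  expect_equal(ex$theta_deg, 110, tolerance = 1e-9)
  # identical values at all radii: same intercept
  d2 <- data.frame(radius = R, cos_theta = rep(-0.3, 4))
  expect_equal(extrapolate_angle(d2)$cos_intercept, -0.3, tolerance = 1e-12)
  # a single radius cannot be extrapolated and is flagged
  one <- extrapolate_angle(data.frame(radius = 10, cos_theta = 0.5))
  expect_false(one$extrapolated)
  expect_equal(one$theta_deg, 60, tolerance = 1e-10)
})

test_that("boundary extraction locates a half-disc within one grid cell", {
  frames <- synthetic_cap_frames(90, 10, contact_height = 0, ly = 8,
                                 n_frames = 4, seed = 31)
  prof <- extract_boundary(frames, species = "dodecane")
  pts <- prof$points[prof$points$keep, ]
  expect_gt(nrow(pts), 20)
  cx <- prof$com[["x"]]
  d <- sqrt((pts$x - cx)^2 + pts$z^2)
  # boundary points sit on the circle to within about one sampling cell
  expect_lt(max(abs(d - 10)), 0.45)
  expect_equal(median(abs(d - 10)), 0, tolerance = 0.25)
})

test_that("a uniform field has no boundary", {
  ff <- default_forcefield()
  st <- water_box(c(8, 8, 8), seed = 32, walled = TRUE)
  expect_error(extract_boundary(list(st), species = "water"),
               "no boundary|fill")
})

test_that("boundary extraction is mirror-symmetric in x", {
  frames <- synthetic_cap_frames(120, 8, contact_height = 0, ly = 6,
                                 n_frames = 3, seed = 33)
  mirrored <- lapply(frames, function(fr) {
    fr$positions[, 1] <- fr$box[1] - fr$positions[, 1]
    fr
  })
  p1 <- extract_boundary(frames, species = "dodecane")
  p2 <- extract_boundary(mirrored, species = "dodecane")
  # left boundary maps onto the right boundary, reflected about the CoM
  l1 <- p1$points[p1$points$side == "left", ]
  r2 <- p2$points[p2$points$side == "right", ]
  shared <- intersect(l1$z, r2$z)
  expect_gt(length(shared), 10)
  d1 <- l1$x[match(shared, l1$z)] - p1$com[["x"]]
  d2 <- r2$x[match(shared, r2$z)] - p2$com[["x"]]
  expect_equal(d1, -d2, tolerance = 0.21)  # one grid cell
})

test_that("droplet configurations respect the counting rule", {
  ff <- default_forcefield()
  st <- build_droplet_config(c(25, 10, 25), c(8, 10, 8), ff, seed = 34)
  n_dod <- sum(st$species %in% 2:3)
  expect_equal(n_dod, 7 * round(3.27 * 8 * 10 * 8 / 7))
  n_wat <- sum(st$species == 1)
  expect_equal(n_wat, round(3 * (25 * 10 * 25 - 8 * 10 * 8)))
  expect_true(st$walled)
  # zero droplet volume: pure bath
  st0 <- build_droplet_config(c(10, 6, 10), c(0, 6, 0), ff, seed = 35)
  expect_equal(sum(st0$species %in% 2:3), 0)
  expect_error(build_droplet_config(c(10, 6, 10), c(12, 6, 4), ff),
               "fit")
})
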