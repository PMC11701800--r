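test_that("plane Poiseuille reproduces the flat-chamber reference values", {
  pp <- analytic_plane_poiseuille("5 uL/min", 3e-3, 0.5e-3, z = 10e-6)
  expect_equal(pp$tau_floor, 0.46e-3, tolerance = 1e-3)
  expect_equal(pp$u_x, 6.53e-6, tolerance = 1e-3)
  expect_equal(analytic_plane_poiseuille("5 uL/min", 3e-3, 0.5e-3,
                                         z = 0)$u_x, 0)
  expect_error(analytic_plane_poiseuille("5 uL/min", 3e-3, 0.5e-3,
                                         z = 1e-3), "outside")
})

test_that("rectangular duct series integrates to Q and has known limits", {
  f <- fluid_properties()
  Q <- parse_quantity("5 uL/min")
  ny <- 160; nz <- 80
  yy <- seq(-1.5e-3 + 1.5e-3 / ny, 1.5e-3 - 1.5e-3 / ny, length.out = ny)
  zz <- seq(2.5e-6, 5e-4 - 2.5e-6, length.out = nz)
  U <- outer(yy, zz, function(a, b)
    analytic_rect_duct(Q, 3e-3, 5e-4, f, y = a, z = b))
  Qnum <- sum(U) * (3e-3 / ny) * (5e-4 / nz)
  expect_equal(Qnum, Q, tolerance = 1e-3)
  # wide-duct limit recovers plane Poiseuille at the centreline
  u_wide <- analytic_rect_duct(Q, 50e-3, 5e-4, f, y = 0, z = 2.5e-4)
  u_plane <- analytic_plane_poiseuille(Q, 50e-3, 5e-4, f, z = 2.5e-4)$u_x
  expect_equal(u_wide, u_plane, tolerance = 0.01)
  # 6:1 duct centreline floor shear exceeds the plane mean by the
  # 200-term series factor, and 50 terms already agree with 200
  d50 <- analytic_rect_duct(Q, 3e-3, 5e-4, f, y = 0, z = 0,
                            derivative = TRUE, nterms = 50)$dudz
  d200 <- analytic_rect_duct(Q, 3e-3, 5e-4, f, y = 0, z = 0,
                             derivative = TRUE, nterms = 200)$dudz
  expect_equal(d50, d200, tolerance = 1e-2) # wall derivative converges slowly
  tau_plane <- analytic_plane_poiseuille(Q, 3e-3, 5e-4, f)$tau_floor
  factor <- f$mu * d200 / tau_plane
  expect_gt(factor, 1) # side walls raise the centreline shear
  expect_lt(factor, 1.2)
  expect_error(analytic_rect_duct(Q, 3e-3, 5e-4, f, y = 0, z = 1e-4,
                                  nterms = 0), "truncation")
  expect_error(analytic_rect_duct(Q, 3e-3, 5e-4, f, y = 2e-3, z = 1e-4),
               "outside")
})

test_that("Reynolds number stays below 0.1 for all candidate flow rates", {
  for (q in c(1, 3, 5, 10)) {
    expect_lt(reynolds_number(sprintf("%d uL/min", q), 3e-3, 0.5e-3), 0.1)
  }
})

test_that("quantity parsing normalises unit-suffixed strings to SI", {
  expect_equal(parse_quantity("5 uL/min"), 8.3333e-11, tolerance = 1e-4)
  expect_equal(parse_quantity("500 um"), 5e-4)
  expect_equal(parse_quantity("0.76 mm"), 7.6e-4)
  expect_equal(parse_quantity(2e-9), 2e-9)
  expect_equal(parse_quantity("0.1 mPa"), 1e-4)
  expect_error(parse_quantity("5 parsec"), "unknown unit")
  expect_error(parse_quantity("abc"), "parse")
})
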