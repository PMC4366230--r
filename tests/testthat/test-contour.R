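square40 <- function() {
  outline_polygon(rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40)))
}

regular_circle <- function(n = 32, r = 50, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline_polygon(cbind(r * cos(th) + center[1], r * sin(th) + center[2]))
}

test_that("outline resampling spaces vertices equally along the perimeter", {
  rs <- resample_outline(square40(), 10)
  expect_equal(nrow(rs), 16)   # 160 um perimeter / 10 um
  seg <- sqrt(rowSums((unclass(rs)[c(2:16, 1), ] - unclass(rs))^2))
  expect_true(all(abs(seg - 10) <= 5 + 1e-9))
  # perimeter is preserved to 1% at fine spacing, on an irregular outline
  # (lobed, with features coarser than the sampling distance)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  irr <- outline_polygon(cbind((30 + 5 * sin(3 * th)) * cos(th),
                               (30 + 5 * sin(3 * th)) * sin(th)))
  per <- function(p) {
    xy <- unclass(p)
    sum(sqrt(rowSums((xy[c(2:nrow(xy), 1), ] - xy)^2)))
  }
  rs2 <- resample_outline(irr, per(irr) / 60)
  expect_lt(abs(per(rs2) - per(irr)) / per(irr), 0.01)
  expect_error(resample_outline(square40(), 60), "spacing")
})

test_that("the beta spline of a regular polygon hugs the circle", {
  spl <- beta_spline(regular_circle(), beta1 = 1, beta2 = 0)
  rad <- sqrt(rowSums(unclass(spl)^2))
  expect_true(all(abs(rad - 50) < 0.5))
  # closed: first sample repeated at the end
  expect_equal(unclass(spl)[1, ], unclass(spl)[nrow(spl), ])
})

test_that("spline samples average to the control-polygon centroid", {
  set.seed(22)
  th <- sort(runif(12, 0, 2 * pi))
  poly <- outline_polygon(cbind(40 * cos(th) + 10, 25 * sin(th) - 5))
  spl <- beta_spline(poly)
  ctr_poly <- colMeans(unclass(poly))
  ctr_spl <- colMeans(unclass(spl)[-nrow(spl), ])
  expect_lt(sqrt(sum((ctr_spl - ctr_poly)^2)) /
              sqrt(sum(ctr_poly^2)), 0.02)
})

test_that("tension pulls the curve toward the control polygon", {
  poly <- regular_circle(n = 8, r = 30)
  dist_to_poly <- function(spl) {
    xy <- unclass(spl); ctl <- unclass(poly)
    max(vapply(seq_len(nrow(xy)), function(i) {
      min(sqrt(rowSums(sweep(ctl, 2, xy[i, ])^2)))
    }, 1))
  }
  d0 <- dist_to_poly(beta_spline(poly, beta2 = 0))
  d100 <- dist_to_poly(beta_spline(poly, beta2 = 100))
  expect_lt(d100, d0)
  expect_error(beta_spline(poly, beta1 = Inf), "finite")
  expect_error(beta_spline(outline_polygon(rbind(c(0, 0), c(1, 0),
                                                 c(1, 1)))), "4 control")
})

test_that("B-spline samples stay inside the control-point convex hull", {
  set.seed(23)
  for (case in 1:5) {
    th <- sort(runif(10, 0, 2 * pi))
    r <- runif(10, 10, 40)
    poly <- outline_polygon(cbind(r * cos(th), r * sin(th)))
    spl <- unclass(beta_spline(poly))
    hull <- chull(unclass(poly))
    hxy <- unclass(poly)[hull, ]
    n <- nrow(hxy)
    area2 <- sum(hxy[, 1] * hxy[c(2:n, 1), 2] -
                   hxy[c(2:n, 1), 1] * hxy[, 2])
    if (area2 < 0) hxy <- hxy[n:1, ]   # force counterclockwise
    # inside test: every sample on the left of every hull edge
    inside <- rep(TRUE, nrow(spl))
    for (e in seq_len(n)) {
      a <- hxy[e, ]; b <- hxy[e %% n + 1, ]
      cr <- (b[1] - a[1]) * (spl[, 2] - a[2]) -
        (b[2] - a[2]) * (spl[, 1] - a[1])
      inside <- inside & (cr >= -1e-9)
    }
    expect_true(all(inside))
  }
})

test_that("splines are equivariant under rigid motions", {
  set.seed(24)
  th <- sort(runif(14, 0, 2 * pi))
  poly <- cbind(35 * cos(th), 20 * sin(th))
  ang <- 0.7; shift <- c(12, -8)
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  moved <- sweep(poly %*% t(rot), 2, shift, `+`)
  s1 <- unclass(beta_spline(outline_polygon(poly)))
  s2 <- unclass(beta_spline(outline_polygon(moved)))
  expect_lt(max(abs(sweep(s1 %*% t(rot), 2, shift, `+`) - s2)), 1e-9)
})

test_that("outline stacking orders by z and flags gaps", {
  curves <- lapply(c(1, 2, 3), function(k) {
    beta_spline(regular_circle(center = c(60, 60)) |>
                  (\(p) { attr(p, "z") <- k; p })())
  })
  stk <- stack_outlines(curves, z_step = 10)
  expect_equal(stk$z_index, c(1, 2, 3))
  expect_equal(diff(stk$z_um), c(10, 10))
  expect_length(stk$gaps, 0)
  stk2 <- stack_outlines(curves[c(1, 3)], z_step = 10)
  expect_equal(stk2$gaps, 2)
  expect_length(stack_outlines(list())$curves, 0)
  dup <- curves[c(1, 1)]
  expect_error(stack_outlines(dup, 10), "duplicate z")
})

test_that("outline CSV round-trips through read/write", {
  polys <- list(
    outline_polygon(rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20)),
                    t = 1, z = 3, object = 2),
    outline_polygon(rbind(c(5, 5), c(15, 6), c(10, 18)),
                    t = 1, z = 4, object = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_outlines(polys, path)
  back <- read_outlines(path)
  expect_length(back, 2)
  expect_equal(unclass(back[[1]])[, 1:2],
               unclass(polys[[1]])[, 1:2], ignore_attr = TRUE)
  expect_equal(attr(back[[2]], "z"), 4L)
})

test_that("filopod polylines keep their anchor and need two points", {
  fp <- filopod_polyline(rbind(c(0, 0), c(5, 8), c(9, 12)), anchor = 3,
                         t = 2, z = 7)
  expect_equal(attr(fp, "anchor"), 3L)
  expect_error(filopod_polyline(rbind(c(0, 0))), "2 points")
})
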