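grid_img <- function(data, spacing = 0.15) {
  nz <- nrow(data); nx <- ncol(data)
  oa_image(data, x = (seq_len(nx) - 0.5) * spacing,
           z = (seq_len(nz) - 0.5) * spacing, spacing = spacing, 757)
}

test_that("bright-object segmentation finds tubes and not background", {
  set.seed(6)
  nz <- 200; nx <- 200
  bg <- matrix(1 + 0.05 * rnorm(nz * nx), nz)
  img <- grid_img(bg)
  tubes <- outer((img$z - 15)^2, (img$x - 10)^2, "+") <= 1.2^2 |
           outer((img$z - 15)^2, (img$x - 20)^2, "+") <= 1.2^2
  img$data[tubes] <- img$data[tubes] + 5
  m <- segment_bright(img)
  expect_gt(sum(m & tubes) / sum(tubes), 0.9)
  expect_lt(sum(m & !tubes) / sum(!tubes), 0.05)
  # uniform image and an infinite threshold give empty masks
  expect_false(any(segment_bright(grid_img(matrix(2, 50, 50)))))
  expect_false(any(segment_bright(img, threshold_sigma = 1e9)))
})

test_that("row-mean depth normalization flattens exponential backgrounds", {
  nz <- 240; nx <- 80
  z <- (seq_len(nz) - 0.5) * 0.15
  bg <- matrix(0.04 * exp(-z / 9), nz, nx)
  img <- grid_img(bg)
  out <- normalize_depth(img)
  expect_equal(out$data, matrix(1, nz, nx), tolerance = 1e-6)
  # uniform image unchanged up to the global scale
  out_u <- normalize_depth(grid_img(matrix(0.3, nz, nx)), scale = 0.3)
  expect_equal(out_u$data, matrix(0.3, nz, nx))
  # vessel of local contrast k keeps value k at every depth 13-32 mm
  for (zd in c(13, 20, 26, 32)) {
    d <- matrix(0.04 * exp(-z / 9), nz, nx)
    vessel <- outer((z - zd)^2, ((seq_len(nx) - 0.5) * 0.15 - 6)^2, "+") <= 1
    d[vessel] <- 5 * d[vessel]
    im <- grid_img(d)
    out_v <- normalize_depth(im, mask = vessel)
    expect_equal(mean(out_v$data[vessel]), 5, tolerance = 0.1 * 5)
  }
})

test_that("fully masked rows are interpolated from neighbours", {
  nz <- 60; nx <- 40
  z <- (seq_len(nz) - 0.5) * 0.15
  img <- grid_img(matrix(exp(-z / 9), nz, nx))
  mask <- matrix(FALSE, nz, nx); mask[30:32, ] <- TRUE
  out <- normalize_depth(img, mask)
  expect_equal(attr(out, "interpolated_rows"), 30:32)
  expect_equal(out$data[31, 1], 1, tolerance = 5e-3)
  expect_error(normalize_depth(img, matrix(TRUE, nz, nx)), "no usable")
  # analytic profile mode divides by the supplied profile
  prof <- exp(-z / 9)
  out_p <- normalize_depth(img, profile = prof)
  expect_equal(out_p$data, matrix(1, nz, nx), tolerance = 1e-12)
  expect_error(normalize_depth(img, profile = prof[-1]), "one value per")
})

test_that("dual-wavelength unmixing is an exact inverse", {
  tab <- chromophore_table()
  # algebraic identities for pure blood
  mk_pair <- function(so2, thb) {
    m <- lapply(c(757, 1064), function(wl) {
      mu <- thb * (so2 * extinction(tab, wl, "HbO2") +
                     (1 - so2) * extinction(tab, wl, "Hb"))
      oa_image(matrix(mu, 10, 10), 1:10, 1:10, 1, wl)
    })
    unmix(m[[1]], m[[2]])
  }
  pure_o <- mk_pair(1, 0.8)
  expect_equal(pure_o$so2, matrix(1, 10, 10))
  expect_equal(pure_o$thb, matrix(0.8, 10, 10))
  pure_d <- mk_pair(0, 1.3)
  expect_equal(pure_d$so2, matrix(0, 10, 10))
  expect_equal(pure_d$thb, matrix(1.3, 10, 10))
  mid <- mk_pair(0.5, 1)
  expect_equal(mid$so2, matrix(0.5, 10, 10), tolerance = 1e-12)
  # property: random sO2/tHb fields recovered to machine precision
  set.seed(7)
  for (k in 1:10) {
    so2 <- matrix(runif(400), 20)
    thb <- matrix(runif(400, 0.2, 2), 20)
    imgs <- lapply(c(757, 1064), function(wl) {
      mu <- thb * (so2 * extinction(tab, wl, "HbO2") +
                     (1 - so2) * extinction(tab, wl, "Hb"))
      oa_image(mu, 1:20, 1:20, 1, wl)
    })
    fm <- unmix(imgs[[1]], imgs[[2]], thb_floor_frac = 0)
    expect_equal(fm$so2, so2, tolerance = 1e-10)
    expect_equal(fm$thb, thb, tolerance = 1e-10)
  }
  # singular extinction matrix refuses to unmix
  sing <- chromophore_table()
  sing$eps_HbO2 <- 2 * sing$eps_Hb
  i1 <- oa_image(matrix(1, 4, 4), 1:4, 1:4, 1, 757)
  i2 <- oa_image(matrix(1, 4, 4), 1:4, 1:4, 1, 1064)
  expect_error(unmix(i1, i2, table = sing), "singular")
  # low-tHb pixels are marked undefined
  lo <- mk_pair(0.5, 1)
  lo2 <- lo
  imgs <- lapply(c(757, 1064), function(wl) {
    mu <- matrix(extinction(tab, wl, "Hb"), 10, 10)
    mu[1, 1] <- mu[1, 1] * 1e-4
    oa_image(mu, 1:10, 1:10, 1, wl)
  })
  fm <- unmix(imgs[[1]], imgs[[2]])
  expect_true(is.na(fm$so2[1, 1]))
  expect_false(fm$valid[1, 1])
})

test_that("statistical mapping standardizes against the reference region", {
  set.seed(8)
  m <- matrix(rnorm(2500, 5, 2), 50)
  ref <- matrix(FALSE, 50, 50); ref[1:20, ] <- TRUE
  z <- statistical_map(m, ref)
  mu <- mean(m[ref]); s <- sd(m[ref])
  expect_equal(z[ref][1], (m[ref][1] - mu) / s)
  expect_equal(mean(z[ref]), 0, tolerance = 1e-12)
  expect_equal(sd(z[ref]), 1, tolerance = 1e-12)
  # a pixel at the reference mean maps to 0; mean + 2 sd maps to 2
  m2 <- m; m2[30, 2] <- mu; m2[30, 3] <- mu + 2 * s
  z2 <- statistical_map(m2, ref)
  expect_equal(z2[30, 2], 0)
  expect_equal(z2[30, 3], 2)
  const <- matrix(1, 50, 50)
  expect_error(statistical_map(const, ref), "variance")
  expect_error(statistical_map(m, matrix(FALSE, 50, 50)), "empty")
})
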