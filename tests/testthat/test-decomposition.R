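test_that("per-pixel solve inverts the Beer-Lambert system", {
  dg <- attenuation_matrix(diag(c(2, 3, 4)), c(780, 808, 980),
                           c("a", "b", "c"))
  expect_equal(unname(decompose_pixel(c(1.0, 1.5, 2.0), dg)$thickness),
               c(0.5, 0.5, 0.5))
  expect_equal(unname(decompose_pixel(c(0, 0, 0), dg)$thickness), c(0, 0, 0))

  # frozen oracle: the forward product of the chicken matrix with
  # (0.5, 0.2, 0.1) cm generates the input; the solve must invert it
  m <- chicken_mat()
  b <- as.vector(m$values %*% c(0.5, 0.2, 0.1))
  expect_equal(b, c(3.2058, 2.7847, 2.4843), tolerance = 1e-12)
  expect_equal(unname(decompose_pixel(b, m)$thickness), c(0.5, 0.2, 0.1),
               tolerance = 1e-10)

  sing <- attenuation_matrix(rbind(c(1, 2, 3), c(2, 4, 6), c(1, 1, 1)),
                             c(780, 808, 980), c("a", "b", "c"))
  expect_error(decompose_pixel(c(1, 2, 3), sing), "determinant")
})

test_that("whole-frame decomposition broadcasts the pixel solve", {
  m <- chicken_mat()
  b <- as.vector(m$values %*% c(0.5, 0.2, 0.1))
  vals <- array(rep(exp(-b), each = 16), c(4, 4, 3))
  st <- new_transmittance_stack(vals, m$wavelengths_nm, matrix(TRUE, 4, 4))
  res <- decompose_stack(log_inverse_transmittance(st), m)
  for (j in 1:3)
    expect_equal(res$thickness_maps$values[, , j],
                 matrix(c(0.5, 0.2, 0.1)[j], 4, 4), tolerance = 1e-10)
  expect_equal(res$negatives_fraction, 0)
})

test_that("an all-invalid frame yields all no-data with a warning", {
  m <- chicken_mat()
  st <- new_transmittance_stack(array(NA_real_, c(2, 2, 3)),
                                m$wavelengths_nm, matrix(FALSE, 2, 2))
  expect_warning(res <- decompose_stack(log_inverse_transmittance(st), m),
                 "no valid pixels")
  expect_true(all(is.na(res$thickness_maps$values)))
  expect_equal(res$negatives_fraction, 0)
})

test_that("wavelength order mismatches are an error, never silently reordered", {
  m <- chicken_mat()
  st <- new_transmittance_stack(array(0.5, c(2, 2, 3)),
                                c(808, 780, 980), matrix(TRUE, 2, 2))
  expect_error(decompose_stack(log_inverse_transmittance(st), m),
               "wavelength order mismatch")
})

test_that("negativity policy clips or passes raw values through", {
  m <- attenuation_matrix(diag(3), c(1, 2, 3), c("a", "b", "c"))
  vals <- array(exp(-c(-0.01, 0.3, 0.2)), c(1, 1, 3))  # lnT^-1 = (-0.01, .3, .2)
  st <- new_transmittance_stack(vals, c(1, 2, 3), matrix(TRUE, 1, 1))
  fld <- log_inverse_transmittance(st)
  fld$values <- array(c(-0.01, 0.3, 0.2), c(1, 1, 3))  # force a negative
  res <- decompose_stack(fld, m)
  expect_equal(as.vector(postprocess(res, "clip_zero")$values), c(0, 0.3, 0.2))
  expect_equal(as.vector(postprocess(res, "keep_raw")$values),
               c(-0.01, 0.3, 0.2))
  expect_equal(res$negatives_fraction, 1)
  expect_error(postprocess(res, "nonsense"))

  # all-nonnegative raw values are unchanged under both policies
  fld$values <- array(c(0.1, 0.3, 0.2), c(1, 1, 3))
  res2 <- decompose_stack(fld, m)
  expect_equal(postprocess(res2, "clip_zero")$values,
               postprocess(res2, "keep_raw")$values)
})

test_that("thickness renders use the inverse-video convention", {
  map <- matrix(c(0, 0.5, 1.0, NA), 2, 2)
  img <- render_thickness_image(map, display_max = 1.0)
  expect_equal(img$pixels[1, 1], 255)  # zero thickness: white
  expect_equal(img$pixels[1, 2], 0)    # display_max: black
  # half scale: 127.5 rounds half away from zero to 128
  expect_equal(img$pixels[2, 1], 128)
  expect_equal(img$pixels[2, 2], 128)  # no-data sentinel mid-gray
  expect_error(render_thickness_image(map, display_max = -1), "positive")
})

test_that("noise-free phantom decomposition reproduces ground truth exactly", {
  m <- chicken_mat()
  out <- simulate_phantom(exact_phantom(shape = c(32L, 32L)), m)
  res <- decompose_phantom(out, m)
  met <- recovery_metrics(res$thickness_maps, out$ground_truth)
  expect_lt(max(met$max_abs_err_cm), 1e-6)
  # total-thickness consistency: per-pixel sum over tissue maps equals the
  # generating total thickness
  tot_pred <- apply(res$thickness_maps$values, c(1, 2), sum)
  tot_true <- apply(out$ground_truth$values, c(1, 2), sum)
  expect_lt(max(abs(tot_pred - tot_true), na.rm = TRUE), 1e-6)
})

test_that("permuting tissue columns permutes the output maps identically", {
  m <- chicken_mat()
  out <- simulate_phantom(exact_phantom(shape = c(16L, 16L)), m)
  stack <- transmittance_stack(out$object_images, out$reference_images)
  fld <- log_inverse_transmittance(stack)
  res <- decompose_stack(fld, m)
  perm <- c(3, 1, 2)
  mp <- attenuation_matrix(m$values[, perm], m$wavelengths_nm,
                           m$tissue_labels[perm])
  resp <- decompose_stack(fld, mp)
  expect_equal(resp$thickness_maps$values,
               res$thickness_maps$values[, , perm], tolerance = 1e-10)

  # permuting wavelength rows together with the stack slices is a no-op
  rperm <- c(2, 3, 1)
  mr <- attenuation_matrix(m$values[rperm, ], m$wavelengths_nm[rperm],
                           m$tissue_labels)
  fldr <- fld
  fldr$values <- fld$values[, , rperm]
  fldr$wavelengths_nm <- fld$wavelengths_nm[rperm]
  resr <- decompose_stack(fldr, mr)
  expect_equal(resr$thickness_maps$values, res$thickness_maps$values,
               tolerance = 1e-10)
})

test_that("single-tissue decomposition reduces to -ln(T)/mu", {
  mu <- 3.1
  m1 <- attenuation_matrix(matrix(mu), 808, "gel")
  T_ <- matrix(seq(0.2, 0.9, length.out = 12), 3, 4)
  st <- new_transmittance_stack(array(T_, c(3, 4, 1)), 808,
                                matrix(TRUE, 3, 4))
  res <- decompose_stack(log_inverse_transmittance(st), m1)
  expect_equal(res$thickness_maps$values[, , 1], -log(T_) / mu,
               tolerance = 1e-12)
})

test_that("thickness error grows with the matrix condition number", {
  m0 <- chicken_mat()$values
  msing <- m0
  msing[2, ] <- m0[1, ] * sum(m0[2, ]) / sum(m0[1, ])  # proportional rows
  d_true <- c(0.5, 0.2, 0.1)
  set.seed(101)
  noise <- matrix(rnorm(3 * 500, sd = 0.02), 3)
  errs <- conds <- numeric(0)
  for (t in c(0, 0.7, 0.95)) {
    mt <- (1 - t) * m0 + t * msing
    b <- as.vector(mt %*% d_true)
    errs <- c(errs, mean(abs(solve(mt, b + noise) - d_true)))
    conds <- c(conds, kappa(mt, exact = TRUE))
  }
  expect_true(all(diff(conds) > 0))
  expect_true(all(diff(errs) > 0))
})
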