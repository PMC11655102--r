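test_that("isotropic tensor profile is constant within offset classes", {
  fld <- toy_tensor_field(c(4, 4, 4))
  sch <- build_scheme(3)
  pr <- dti_profile(fld, sch)
  # interior voxel with all 26 neighbors present
  full <- which(rowSums(pr$present) == 26)[1]
  v <- pr$values[full, ]
  cls <- rowSums(sch$offsets^2)  # 1 face, 2 edge, 3 corner
  expect_equal(diff(range(v[cls == 1])), 0, tolerance = 1e-15)
  expect_equal(diff(range(v[cls == 2])), 0, tolerance = 1e-15)
  expect_equal(diff(range(v[cls == 3])), 0, tolerance = 1e-15)
  expect_gt(min(v[cls == 1]), max(v[cls == 2]))
  expect_gt(min(v[cls == 2]), max(v[cls == 3]))
  # frozen oracle: (2*pi)^(-3/2) * exp(-q/2) for q = 1, 2, 3
  expect_equal(unname(v[cls == 1][1]), 0.03851083689074894, tolerance = 1e-14)
  expect_equal(unname(v[cls == 2][1]), 0.02335800330543158, tolerance = 1e-14)
  expect_equal(unname(v[cls == 3][1]), 0.01416734515441329, tolerance = 1e-14)
})

test_that("anisotropic tensor favors its principal axis; value matches the Gaussian-model oracle", {
  # T = diag(1, 0.2, 0.2), unit voxel
  fld <- toy_tensor_field(c(4, 4, 4), tensor = c(1, 0, 0.2, 0, 0, 0.2))
  sch <- build_scheme(3)
  pr <- dti_profile(fld, sch)
  full <- which(rowSums(pr$present) == 26)[1]
  v <- pr$values[full, ]
  kx <- which(apply(sch$offsets, 1L, function(o) all(o == c(1, 0, 0))))
  ky <- which(apply(sch$offsets, 1L, function(o) all(o == c(0, 1, 0))))
  expect_gt(v[kx], v[ky])
  # frozen high-precision direct evaluations of the Gaussian model
  expect_equal(unname(v[kx]), 0.19255418445374472, tolerance = 1e-14)
  expect_equal(unname(v[ky]), 0.026059375091442505, tolerance = 1e-14)
})

test_that("tensor profile respects lattice-preserving rotations", {
  # rotating tensor and offsets together by 90 deg about z maps the
  # profile onto itself with permuted directions
  fld_x <- toy_tensor_field(c(3, 3, 3), tensor = c(1, 0, 0.2, 0, 0, 0.3))
  fld_y <- toy_tensor_field(c(3, 3, 3), tensor = c(0.2, 0, 1, 0, 0, 0.3))
  sch <- build_scheme(3)
  px <- dti_profile(fld_x, sch)$values
  py <- dti_profile(fld_y, sch)$values
  rot <- function(o) c(-o[2], o[1], o[3])  # 90 deg about z
  mapidx <- apply(sch$offsets, 1L, function(o) {
    ro <- rot(o)
    which(apply(sch$offsets, 1L, function(q) all(q == ro)))
  })
  center <- which(rowSums(dti_profile(fld_x, sch)$present) == 26)[1]
  expect_equal(px[center, ], py[center, mapidx], tolerance = 1e-14)
})

test_that("singular tensors are rejected with voxel coordinates", {
  fld <- toy_tensor_field(c(3, 3, 3), tensor = c(1, 0, 1, 0, 0, 0))
  expect_error(dti_profile(fld, build_scheme(3)), "voxel \\(1, 1, 1\\)")
})

test_that("cap half-angle follows the exact cap-area inversion", {
  sch <- build_scheme(3)
  dirs <- sphere_directions(642)
  caps <- cap_membership(dirs, sch)
  expect_equal(caps$cos_threshold, 12 / 13)
  # a sample exactly along a scheme direction is in that cap
  caps2 <- cap_membership(rbind(sch$directions, -sch$directions), sch)
  for (k in seq_len(26)) expect_true(k %in% caps2$members[[k]])
})

test_that("cap membership matches brute-force angle checks", {
  sch <- build_scheme(3)
  dirs <- sphere_directions(642)
  caps <- cap_membership(dirs, sch)
  theta <- acos(1 - sch$solid_angle / (2 * pi))
  for (k in seq_len(26)) {
    ang <- acos(pmin(1, pmax(-1, dirs %*% sch$directions[k, ])))
    expect_identical(caps$members[[k]], which(ang <= theta + 1e-12))
  }
})

test_that("too few samples produce an empty-cap error naming a direction", {
  sch5 <- build_scheme(5)
  # 6 axis directions cannot cover all 98 caps
  axes <- rbind(diag(3), -diag(3))
  expect_error(cap_membership(axes, sch5), "empty spherical cap")
})

test_that("constant ODFs give p = c^n in every direction", {
  ph <- make_tissue_phantom(c(12, 12, 12), bundle_radius = 1, seed = 1)
  fld <- make_odf_field(ph, sharpness = 1, seed = 1)
  bg <- which(ph$labels[fld$mask_index] == 1L)[1]
  fld$amplitudes[bg, ] <- 3
  pr <- odf_profile(fld, build_scheme(3), exponent_n = 2)
  expect_equal(unname(pr$values[bg, pr$present[bg, ]]),
               rep(9, sum(pr$present[bg, ])))
})

test_that("two-level ODF profile matches hand computation from cap counts", {
  sch <- build_scheme(3)
  dirs <- sphere_directions(642)
  caps <- cap_membership(dirs, sch)
  # amplitudes: a = 2 inside cap of +x (and its antipode), b = 0.5 elsewhere
  kx <- which(apply(sch$offsets, 1L, function(o) all(o == c(1, 0, 0))))
  inx <- union(caps$members[[kx]], caps$members[[sch$antipode[kx]]])
  amp <- rep(0.5, nrow(dirs))
  amp[inx] <- 2
  labels <- array(2L, c(3, 3, 3))
  anis <- array(0.5, c(3, 3, 3))
  fld <- structure(
    list(amplitudes = matrix(amp, 27, length(amp), byrow = TRUE),
         directions = dirs, mask_index = 1:27, dim = c(3L, 3L, 3L),
         voxel_size = c(1, 1, 1),
         phantom = structure(list(labels = labels, anisotropy = anis,
                                  voxel_size = c(1, 1, 1)),
                             class = "tissue_phantom")),
    class = "odf_field"
  )
  pr <- odf_profile(fld, sch, exponent_n = 2)
  center <- which(rowSums(pr$present) == 26)[1]
  for (k in seq_len(26)) {
    mem <- caps$members[[k]]
    expected <- mean(amp[mem]^2)
    expect_equal(unname(pr$values[center, k]), expected, tolerance = 1e-14)
  }
})

test_that("single-peak ODFs are maximal along the nearest scheme direction", {
  ph <- make_tissue_phantom(c(14, 14, 14), bundle_axis = "y",
                            bundle_radius = 2, seed = 2)
  fld <- make_odf_field(ph, sharpness = 12, seed = 2)
  pr <- odf_profile(fld, build_scheme(3))
  wm <- which(ph$labels[fld$mask_index] == 2L)
  center <- wm[which(rowSums(pr$present[wm, ]) == 26)[1]]
  best <- which.max(pr$values[center, ])
  expect_equal(abs(build_scheme(3)$directions[best, 2]), 1)
})

test_that("antipodally symmetric ODFs give antipodally symmetric profiles", {
  fx <- odf_fixture()
  pr <- fx$profile3
  sch <- fx$scheme3
  full <- which(rowSums(pr$present) == 26)
  some <- full[seq(1, length(full), by = 40)]
  expect_equal(pr$values[some, ], pr$values[some, sch$antipode],
               tolerance = 1e-12)
})

test_that("raising the exponent sharpens non-constant profiles", {
  fx <- odf_fixture()
  p1 <- odf_profile(fx$field, fx$scheme3, exponent_n = 1)
  p3 <- odf_profile(fx$field, fx$scheme3, exponent_n = 3)
  wm <- which(fx$phantom$labels[fx$field$mask_index] == 2L)
  r <- wm[which(rowSums(p1$present[wm, ]) == 26)[1]]
  ratio1 <- max(p1$values[r, ]) / mean(p1$values[r, ])
  ratio3 <- max(p3$values[r, ]) / mean(p3$values[r, ])
  expect_gt(ratio3, ratio1)
  expect_error(odf_profile(fx$field, fx$scheme3, exponent_n = 0), "> 0")
})
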