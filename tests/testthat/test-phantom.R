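test_that("tissue phantom has the designed geometry and contrast", {
  ph <- make_tissue_phantom(c(20, 20, 20), bundle_axis = "x",
                            bundle_radius = 3, bundle_level = 0.8, seed = 1)
  expect_true(sum(ph$labels == 2L) > 0)
  means <- tapply(ph$anisotropy[ph$labels > 0], ph$labels[ph$labels > 0],
                  mean)
  expect_gt(means[["2"]], means[["1"]])  # WM > GM
  expect_gt(means[["2"]], means[["3"]])  # WM > CSF
  expect_true(all(ph$anisotropy[ph$labels == 0L] == 0))
  expect_true(all(ph$anisotropy >= 0 & ph$anisotropy <= 1))
})

test_that("phantom generation is deterministic and rejects bad geometry", {
  a <- make_tissue_phantom(c(20, 20, 20), bundle_radius = 3, seed = 7)
  b <- make_tissue_phantom(c(20, 20, 20), bundle_radius = 3, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$anisotropy, b$anisotropy)
  expect_error(make_tissue_phantom(c(20, 20, 20), bundle_radius = 30),
               "does not fit")
  expect_error(make_tissue_phantom(c(6, 20, 20)), "at least 8")
})

test_that("tensor field aligns bundle tensors and stays SPD", {
  ph <- make_tissue_phantom(c(14, 14, 14), bundle_axis = "x",
                            bundle_radius = 2, seed = 2)
  fld <- make_tensor_field(ph, eigenvalue_ratio = 5, seed = 2)
  is_wm <- ph$labels[fld$mask_index] == 2L
  # principal eigenvector of in-bundle tensors aligns with (1,0,0)
  wm_rows <- which(is_wm)
  dots <- vapply(wm_rows, function(r) {
    v <- fld$tensors[r, ]
    m <- matrix(v[c(1, 2, 4, 2, 3, 5, 4, 5, 6)], 3, 3)
    abs(eigen(m, symmetric = TRUE)$vectors[1, 1])
  }, numeric(1))
  expect_true(all(dots > 0.95))
  # SPD via Cholesky success at every in-mask voxel
  ok <- vapply(seq_len(nrow(fld$tensors)), function(r) {
    v <- fld$tensors[r, ]
    m <- matrix(v[c(1, 2, 4, 2, 3, 5, 4, 5, 6)], 3, 3)
    !inherits(try(chol(m), silent = TRUE), "try-error")
  }, logical(1))
  expect_true(all(ok))
})

test_that("FA matches the eigenvalue formula and vanishes as ratio -> 1", {
  ph <- make_tissue_phantom(c(14, 14, 14), bundle_radius = 2, seed = 3)
  fld <- make_tensor_field(ph, eigenvalue_ratio = 5, seed = 3)
  fa <- fractional_anisotropy(fld)
  # independent evaluation of the standard FA formula from eigenvalues
  some <- seq(1, length(fld$mask_index), by = 17)
  fa_ref <- vapply(some, function(r) {
    v <- fld$tensors[r, ]
    m <- matrix(v[c(1, 2, 4, 2, 3, 5, 4, 5, 6)], 3, 3)
    l <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / sqrt(sum(l^2))
  }, numeric(1))
  expect_equal(fa[fld$mask_index][some], fa_ref, tolerance = 1e-12)

  fld_iso <- make_tensor_field(ph, eigenvalue_ratio = 1 + 1e-9, seed = 3)
  fa_iso <- fractional_anisotropy(fld_iso)
  is_wm <- ph$labels[fld_iso$mask_index] == 2L
  expect_lt(max(fa_iso[fld_iso$mask_index][is_wm]), 1e-8)
})

test_that("non-unit bundle direction is normalized with a warning", {
  ph <- make_tissue_phantom(c(14, 14, 14), bundle_radius = 2, seed = 4)
  expect_warning(
    fld <- make_tensor_field(ph, bundle_direction = c(2, 0, 0), seed = 4),
    "normaliz"
  )
  expect_equal(fld$bundle_direction, c(1, 0, 0))
})

test_that("ODF field peaks along the bundle and is flat in background", {
  ph <- make_tissue_phantom(c(12, 12, 12), bundle_axis = "z",
                            bundle_radius = 2, seed = 5)
  fld <- make_odf_field(ph, sharpness = 10, n_directions = 642, seed = 5)
  labs <- ph$labels[fld$mask_index]
  bg <- which(labs == 1L)[1]
  expect_equal(max(fld$amplitudes[bg, ]) / min(fld$amplitudes[bg, ]), 1)
  wm <- which(labs == 2L)
  for (r in wm[c(1, length(wm))]) {
    peak <- fld$directions[which.max(fld$amplitudes[r, ]), ]
    ang <- acos(min(1, abs(sum(peak * c(0, 0, 1)))))
    expect_lt(ang, 15 * pi / 180)
  }
  # antipodal symmetry of amplitudes
  dirs <- fld$directions
  anti <- match(
    apply(round(-dirs, 10), 1L, paste, collapse = ","),
    apply(round(dirs, 10), 1L, paste, collapse = ",")
  )
  expect_false(anyNA(anti))
  expect_equal(fld$amplitudes[wm[1], ], fld$amplitudes[wm[1], anti])
})

test_that("doubling sharpness increases peak-to-mean amplitude ratio", {
  ph <- make_tissue_phantom(c(14, 14, 14), bundle_radius = 2, seed = 6)
  f1 <- make_odf_field(ph, sharpness = 5, seed = 6)
  f2 <- make_odf_field(ph, sharpness = 10, seed = 6)
  wm <- which(ph$labels[f1$mask_index] == 2L)[1]
  r1 <- max(f1$amplitudes[wm, ]) / mean(f1$amplitudes[wm, ])
  r2 <- max(f2$amplitudes[wm, ]) / mean(f2$amplitudes[wm, ])
  expect_gt(r2, r1)
})

test_that("ODF field rejects insufficient direction counts", {
  ph <- make_tissue_phantom(c(14, 14, 14), bundle_radius = 2, seed = 6)
  expect_error(make_odf_field(ph, n_directions = 40), ">= 60")
})

test_that("graph signals follow the prescribed spectral profile", {
  fx <- dti_fixture()
  dec <- fx$decomp
  C <- dec$C
  # flat profile: expected energy equal across modes 2..C
  flat <- make_graph_signals(dec, spectral_exponent = 0, num_frames = 400,
                             noise_sd = 0, seed = 9)
  sp <- eesd(flat, dec)
  expect_equal(sp$eesd[1], 0)
  expect_lt(max(abs(sp$eesd[2:C] - mean(sp$eesd[2:C]))) /
              mean(sp$eesd[2:C]), 0.5)
  # power-law: fitted log-log slope of the EESD within +-0.3 of -2
  pl <- make_graph_signals(dec, spectral_exponent = 2, num_frames = 200,
                           noise_sd = 0, seed = 10)
  sp2 <- eesd(pl, dec)
  fit <- lm(log(sp2$eesd[2:C]) ~ log(2:C))
  expect_lt(abs(coef(fit)[2] + 2), 0.3)
  # determinism
  again <- make_graph_signals(dec, spectral_exponent = 2, num_frames = 200,
                              noise_sd = 0, seed = 10)
  expect_identical(pl$signals, again$signals)
})

test_that("single-mode signals concentrate all energy at that index", {
  fx <- dti_fixture()
  dec <- fx$decomp
  X <- dec$vectors[, 2, drop = FALSE] %*% matrix(c(2, -1, 0.5), 1, 3)
  sp <- eesd(structure(list(signals = X, frame_count = 3),
                       class = "graph_signal_set"), dec)
  expect_equal(sp$eesd[2], 1, tolerance = 1e-12)
  expect_equal(sum(sp$eesd[-2]), 0, tolerance = 1e-12)
})

test_that("cohorts are reproducible and collapse at zero perturbation", {
  args <- list(shape = c(14, 14, 14), bundle_radius = 2, seed = 3)
  coh0 <- make_cohort(args, num_subjects = 3, perturbation_sd = 0, seed = 5)
  expect_identical(coh0[[1]]$amplitudes, coh0[[2]]$amplitudes)
  expect_identical(coh0[[2]]$amplitudes, coh0[[3]]$amplitudes)
  a <- make_cohort(args, num_subjects = 2, perturbation_sd = 0.05, seed = 8)
  b <- make_cohort(args, num_subjects = 2, perturbation_sd = 0.05, seed = 8)
  expect_identical(a[[2]]$amplitudes, b[[2]]$amplitudes)
  expect_false(identical(a[[1]]$amplitudes, a[[2]]$amplitudes))
})
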