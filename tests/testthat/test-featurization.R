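test_that("Fermi cutoff matches its printed piecewise definition", {
  expect_equal(fermi_cutoff(1.001, alpha_c = 20, r_cut = 1), 0)
  expect_gt(fermi_cutoff(0, alpha_c = 100, r_cut = 1), 0.999)
  # direct substitution at r = r_cut: 1/(1 + e^{-sqrt(alpha_c)})
  expect_equal(fermi_cutoff(1, alpha_c = 100, r_cut = 1),
               1 / (1 + exp(-10)), tolerance = 1e-12)
  # nonincreasing on [0, r_cut], compact support
  r <- seq(0, 1, length.out = 200)
  f <- fermi_cutoff(r, 25, 1)
  expect_true(all(diff(f) <= 0))
  expect_true(all(fermi_cutoff(seq(1.0001, 5, 0.1), 25, 1) == 0))
})

test_that("G2 matches hand-computable cases", {
  p <- symmetry_function("G2", r_s = 0.5, eta = 25, alpha_c = 200,
                         r_cut = 2, rho_N = 1)
  expect_equal(g2(c(0, 0, 0), matrix(numeric(0), 0, 3), p), 0)
  # one point exactly at r_s with a steep cutoff: unnormalized value ~ 1
  one <- matrix(c(0.5, 0, 0), 1, 3)
  expect_equal(g2(c(0, 0, 0), one, p, normalize = FALSE), 1,
               tolerance = 1e-6)
})

test_that("G5 angular factor behaves as printed", {
  p <- symmetry_function("G5", r_s = 1, eta = 50, zeta = 2, lam = -1,
                         alpha_c = 200, r_cut = 3, rho_N = 1)
  center <- c(0, 0, 0)
  expect_equal(g5(center, matrix(c(1, 0, 0), 1, 3), p), 0)  # no pairs
  # collinear pair through the center (theta = pi), lam = -1: factor 2^zeta
  coll <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(g5(center, coll, p, normalize = FALSE), 2^2, tolerance = 1e-4)
  # perpendicular pair: (1 - cos(pi/2))^2 = 1
  perp <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(g5(center, perp, p, normalize = FALSE), 1, tolerance = 1e-4)
})

test_that("symmetry functions are invariant under rigid motions and permutations", {
  p2 <- symmetry_function("G2", r_s = 1, eta = 4, alpha_c = 20, r_cut = 2)
  p5 <- symmetry_function("G5", r_s = 1, eta = 4, zeta = 4, lam = 1,
                          alpha_c = 20, r_cut = 2)
  set.seed(21)
  for (rep in 1:5) {
    cloud <- matrix(rnorm(30, sd = 0.8), 10, 3)
    center <- rnorm(3, sd = 0.2)
    # random rotation via QR of a Gaussian matrix
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    shift <- rnorm(3)
    cl_rot <- sweep(cloud %*% Q, 2, -shift)
    ct_rot <- as.numeric(center %*% Q + shift)
    perm <- sample(nrow(cloud))
    expect_equal(g2(center, cloud, p2), g2(ct_rot, cl_rot, p2),
                 tolerance = 1e-12)
    expect_equal(g2(center, cloud, p2), g2(center, cloud[perm, ], p2),
                 tolerance = 1e-12)
    expect_equal(g5(center, cloud, p5), g5(ct_rot, cl_rot, p5),
                 tolerance = 1e-12)
    expect_equal(g5(center, cloud, p5), g5(center, cloud[perm, ], p5),
                 tolerance = 1e-12)
  }
})

test_that("G2 normalizer follows the closed form and scales as r_s^2", {
  p <- symmetry_function("G2", r_s = 0.5, eta = 25, alpha_c = 20,
                         r_cut = 2, rho_N = 2)
  expect_equal(g2_normalizer(p), 2 * 8 * pi * 0.25 * sqrt(2 / 25))
  p2 <- symmetry_function("G2", r_s = 1, eta = 25, alpha_c = 20,
                          r_cut = 2, rho_N = 2)
  expect_equal(g2_normalizer(p2) / g2_normalizer(p), 4)
  p0 <- symmetry_function("G2", r_s = 0.5, eta = 25, alpha_c = 20,
                          r_cut = 2, rho_N = 0)
  expect_equal(g2_normalizer(p0), 0)
  # stated validity needs r_cut > r_s
  pbad <- symmetry_function("G2", r_s = 3, eta = 25, alpha_c = 20, r_cut = 2)
  expect_warning(g2_normalizer(pbad), "r_cut")
  # the quadrature oracle reports the closed form's accuracy; it is a
  # diagnostic, finite and positive, not an asserted constant
  ratio <- g2_normalizer_ratio(p)
  expect_true(is.finite(ratio) && ratio > 0)
})

test_that("G5 normalizer reproduces the printed zeta algebra", {
  p <- function(z) symmetry_function("G5", r_s = 1, eta = 4, zeta = z,
                                     lam = 1, alpha_c = 20, r_cut = 2,
                                     rho_N = 1)
  v2 <- guidedtps:::v_probe_g2(p(2))
  # zeta = 2: V5 = 2^{-1} V2 * 3!!/2! = (3/4) V2
  expect_equal(guidedtps:::v_probe_g5(p(2)), 0.75 * v2)
  # pair approximation <N>^2/2 stays positive below one atom
  pa <- p(2); pa$rho_N <- 0.5 / v2 / 0.75  # <N_atoms> = 0.5
  expect_equal(g5_normalizer(pa), 0.125, tolerance = 1e-12)
  # normalizer decreases monotonically in zeta at fixed V2
  v5s <- vapply(c(2, 4, 6, 8, 10), function(z) guidedtps:::v_probe_g5(p(z)),
                numeric(1))
  expect_true(all(diff(v5s) < 0))
})

test_that("normalized G2 over ideal-gas clouds has unit mean", {
  # quadrature normalizer: the expected count integral itself
  p <- symmetry_function("G2", r_s = 1, eta = 4, alpha_c = 20, r_cut = 2,
                         rho_N = 1)
  set.seed(22)
  vals <- replicate(1000, {
    cloud <- generate_point_cloud(rho = 1, box_half = 2.5)
    g2(c(0, 0, 0), cloud, p, normalizer_method = "quadrature")
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("rational switch takes its closed-form values", {
  expect_equal(rational_switch(0, 2), 1)
  expect_equal(rational_switch(2, 2), 0.5)         # removable singularity
  expect_equal(rational_switch(4, 2), 63 / 4095, tolerance = 1e-12)
  # equals the unsimplified form away from R0
  r <- c(0.3, 1.1, 2.7)
  expect_equal(rational_switch(r, 2),
               (1 - (r / 2)^6) / (1 - (r / 2)^12), tolerance = 1e-12)
})

test_that("feature augmentation and scaling behave and invert", {
  feats <- tibble::tibble(g1 = c(2, 4, 6), g2 = c(0, 1, 0.5))
  aug <- augment_with_parameters(feats, list(kT = 0.25, sigma = 0.315))
  expect_equal(ncol(aug), 4)
  expect_error(augment_with_parameters(aug, list(kT = 1)), "collision")
  sc <- scale_features(feats, "minmax")
  expect_equal(sc$features$g1, c(0, 0.5, 1))
  back <- unscale_features(sc$features, sc$scaling)
  expect_equal(as.data.frame(back), as.data.frame(feats), tolerance = 1e-12)
  expect_warning(scale_features(tibble::tibble(a = c(1, 1)), "minmax"),
                 "constant")
  # isotropic scaling = dividing by the stored normalizer
  p <- symmetry_function("G2", r_s = 1, eta = 4, alpha_c = 20, r_cut = 2)
  raw <- tibble::tibble(g = c(1, 2, 3))
  iso <- scale_features(raw, "isotropic", normalizers = c(g = g2_normalizer(p)))
  expect_equal(iso$features$g, raw$g / g2_normalizer(p))
  f <- withr::local_tempfile(fileext = ".json")
  write_scaling(sc$scaling, f)
  rec <- read_scaling(f)
  expect_equal(rec$min, sc$scaling$min, tolerance = 1e-12)
})
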