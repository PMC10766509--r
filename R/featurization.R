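#' Fermi distance cutoff
#'
#' Smooth cutoff used inside the symmetry functions:
#' \deqn{f_c(r) = [1 + \exp(\alpha_c (r - r_{cut} - 1/\sqrt{\alpha_c}))]^{-1}}
#' for \eqn{r \le r_{cut}}, and exactly 0 for \eqn{r > r_{cut}}. The
#' \eqn{-1/\sqrt{\alpha_c}} shift places the sigmoid midpoint beyond
#' `r_cut`, so the function keeps a small but finite jump at the cutoff;
#' it is implemented exactly as defined (see the methods vignette).
#'
#' @param r distance(s), >= 0.
#' @param alpha_c cutoff steepness, > 0.
#' @param r_cut cutoff radius, > 0.
#' @return value(s) in `[0, 1]`, nonincreasing in `r`, with compact support.
#' @export
fermi_cutoff <- function(r, alpha_c, r_cut) {
  if (alpha_c <= 0 || r_cut <= 0) abort("alpha_c and r_cut must be > 0")
  out <- 1 / (1 + exp(alpha_c * (r - r_cut - 1 / sqrt(alpha_c))))
  out[r > r_cut] <- 0
  out
}

#' Symmetry-function parameters
#'
#' Parameter record for Behler-style atomic-environment symmetry functions.
#' `G2` probes the radial density of cloud points in a Gaussian shell of
#' radius `r_s` and width controlled by `eta`; `G5` additionally probes the
#' angular distribution of point pairs with sharpness `zeta` (even) and
#' angular sign `lam` (+1 favours 0, -1 favours pi).
#'
#' @param kind `"G2"` or `"G5"`.
#' @param r_s shell radius, >= 0.
#' @param eta shell width parameter, > 0.
#' @param zeta even integer >= 2 (G5 only, limited to <= 16).
#' @param lam +1 or -1 (G5 only).
#' @param alpha_c,r_cut Fermi-cutoff parameters, see [fermi_cutoff()].
#' @param rho_N number density of the probed point species, used by the
#'   isotropic normalizers.
#' @export
symmetry_function <- function(kind = c("G2", "G5"), r_s, eta,
                              zeta = 2L, lam = 1, alpha_c = 20, r_cut = 2,
                              rho_N = 1) {
  kind <- match.arg(kind)
  if (r_s < 0) abort("r_s must be >= 0")
  if (eta <= 0) abort("eta must be > 0")
  if (rho_N < 0) abort("rho_N must be >= 0")
  if (kind == "G5") {
    if (zeta %% 2 != 0 || zeta < 2 || zeta > 16) {
      abort("zeta must be an even integer in [2, 16]")
    }
    if (!lam %in% c(-1, 1)) abort("lam must be +1 or -1")
  }
  structure(list(kind = kind, r_s = r_s, eta = eta, zeta = as.integer(zeta),
                 lam = lam, alpha_c = alpha_c, r_cut = r_cut, rho_N = rho_N),
            class = "symmetry_function")
}

cloud_matrix <- function(cloud) {
  if (is.data.frame(cloud)) cloud <- as.matrix(cloud)
  if (!is.matrix(cloud)) cloud <- matrix(cloud, nrow = length(cloud) > 0)
  cloud
}

#' Radial (G2) symmetry function
#'
#' \deqn{G^2_i = \sum_j e^{-\eta (r_{ij} - r_s)^2} f_c(r_{ij})}
#' summed over cloud points, divided by the isotropic normalizer
#' (the expected count for an ideal-gas cloud of density `rho_N`) unless
#' `normalize = FALSE`.
#'
#' @param center numeric position of the central point.
#' @param cloud matrix/data frame of cloud positions (one row per point);
#'   an empty cloud gives 0.
#' @param params a [symmetry_function()] with `kind = "G2"`.
#' @param normalize divide by [g2_normalizer()]?
#' @param normalizer_method `"closed_form"` or `"quadrature"`, see
#'   [g2_normalizer()].
#' @export
g2 <- function(center, cloud, params, normalize = TRUE,
               normalizer_method = "closed_form") {
  stopifnot(params$kind == "G2")
  cloud <- cloud_matrix(cloud)
  if (nrow(cloud) == 0) return(0)
  rij <- sqrt(rowSums(sweep(cloud, 2, center)^2))
  raw <- sum(exp(-params$eta * (rij - params$r_s)^2) *
               fermi_cutoff(rij, params$alpha_c, params$r_cut))
  if (!normalize) return(raw)
  raw / g2_normalizer(params, method = normalizer_method)
}

#' Radial-angular (G5) symmetry function
#'
#' \deqn{G^5_i = \sum_{j, k > j} (1 + \lambda \cos\vartheta_{ijk})^\zeta
#'   e^{-\eta[(r_{ij}-r_s)^2 + (r_{ik}-r_s)^2]} f_c(r_{ik}) f_c(r_{ij})}
#' over distinct cloud-point pairs, divided by the isotropic pair
#' normalizer unless `normalize = FALSE`. The angle is computed via a
#' clamped arccos of the dot product for float safety.
#'
#' @inheritParams g2
#' @param params a [symmetry_function()] with `kind = "G5"`.
#' @export
g5 <- function(center, cloud, params, normalize = TRUE) {
  stopifnot(params$kind == "G5")
  cloud <- cloud_matrix(cloud)
  n <- nrow(cloud)
  if (n < 2) return(0)
  rel <- sweep(cloud, 2, center)
  rij <- sqrt(rowSums(rel^2))
  fc <- fermi_cutoff(rij, params$alpha_c, params$r_cut)
  gij <- exp(-params$eta * (rij - params$r_s)^2)
  raw <- 0
  for (j in seq_len(n - 1)) {
    if (fc[j] == 0) next
    ks <- seq(j + 1, n)
    cosv <- (rel[ks, , drop = FALSE] %*% rel[j, ]) / (rij[ks] * rij[j])
    cosv <- pmin(pmax(as.numeric(cosv), -1), 1)
    raw <- raw + sum((1 + params$lam * cosv)^params$zeta *
                       gij[j] * gij[ks] * fc[j] * fc[ks])
  }
  if (!normalize) return(raw)
  raw / g5_normalizer(params)
}

#' Isotropic G2 normalizer
#'
#' Expected number of ideal-gas points contributing to an (unnormalized)
#' G2 value: \eqn{\rho_N V^{(2)}_{probe}}. Method `"closed_form"` uses the
#' approximation \eqn{V^{(2)}_{probe} \approx 8 \pi r_s^2 \sqrt{2/\eta}}
#' (stated for small `eta` and `r_cut > r_s`); method `"quadrature"`
#' evaluates the defining integral
#' \eqn{4\pi \int_0^\infty r^2 e^{-\eta (r - r_s)^2} f_c(r) dr}
#' numerically, which is exact for an isotropic cloud at any `eta`.
#'
#' @param params a [symmetry_function()].
#' @param method `"closed_form"` or `"quadrature"`.
#' @export
g2_normalizer <- function(params, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  params$rho_N * v_probe_g2(params, method)
}

v_probe_g2 <- function(params, method = "closed_form") {
  if (method == "closed_form") {
    if (params$r_cut <= params$r_s) {
      warn("closed-form G2 normalizer is stated for r_cut > r_s")
    }
    return(8 * pi * params$r_s^2 * sqrt(2 / params$eta))
  }
  f <- function(r) {
    r^2 * exp(-params$eta * (r - params$r_s)^2) *
      fermi_cutoff(r, params$alpha_c, params$r_cut)
  }
  4 * pi * integrate(f, 0, params$r_cut, rel.tol = 1e-10)$value
}

#' Ratio of the quadrature to the closed-form G2 probe volume
#'
#' Diagnostic oracle quantifying how far the closed-form normalizer is
#' from the defining integral for a given parameter set; reported, never
#' asserted against.
#'
#' @param params a [symmetry_function()].
#' @export
g2_normalizer_ratio <- function(params) {
  v_probe_g2(params, "quadrature") / v_probe_g2(params, "closed_form")
}

double_factorial <- function(n) {
  # iterative double factorial for odd arguments, (-1)!! = 1
  if (n <= 0) return(1)
  out <- 1
  k <- n
  while (k > 0) { out <- out * k; k <- k - 2 }
  out
}

#' Isotropic G5 pair normalizer
#'
#' Expected number of ideal-gas point pairs weighted by the G5 kernel:
#' \eqn{(\rho_N V^{(5)}_{probe})^2 / 2}, with
#' \eqn{V^{(5)}_{probe} = 2^{1-\zeta} V^{(2)}_{probe} (2\zeta-1)!!/\zeta!}.
#' The pair count uses the approximation \eqn{\langle N\rangle^2/2}, which
#' is guaranteed non-negative also for expected counts below one.
#'
#' @inheritParams g2_normalizer
#' @export
g5_normalizer <- function(params, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  v5 <- v_probe_g5(params, method)
  (params$rho_N * v5)^2 / 2
}

v_probe_g5 <- function(params, method = "closed_form") {
  2^(1 - params$zeta) * v_probe_g2(params, method) *
    double_factorial(2 * params$zeta - 1) / factorial(params$zeta)
}

#' Rational switching function for distances
#'
#' \deqn{f(r) = \frac{1 - (r/R_0)^6}{1 - (r/R_0)^{12}}}
#' mapped onto its algebraically simplified form \eqn{1/(1 + (r/R_0)^6)},
#' which removes the singularity at \eqn{r = R_0} (limit value 1/2) and is
#' exact elsewhere. Used to map pairwise distances into (0, 1].
#'
#' @param r distance(s), >= 0.
#' @param R0 switching radius, > 0.
#' @export
rational_switch <- function(r, R0) {
  if (R0 <= 0) abort("R0 must be > 0")
  1 / (1 + (r / R0)^6)
}

#' Augment a feature table with named scalar parameters
#'
#' Appends constant columns (for example thermodynamic or force-field
#' parameters such as temperature, particle size or dispersion energy) to
#' a feature table so that models can be trained across systems or
#' thermodynamic states.
#'
#' @param features a data frame / tibble of features.
#' @param extra named list of scalars; names must not collide with
#'   existing feature names.
#' @return the augmented tibble.
#' @export
augment_with_parameters <- function(features, extra) {
  features <- as_tibble(features)
  if (any(names(extra) %in% names(features))) {
    abort(paste0("feature name collision: ",
                 paste(intersect(names(extra), names(features)),
                       collapse = ", ")))
  }
  for (nm in names(extra)) features[[nm]] <- extra[[nm]]
  features
}

#' Scale a feature table into approximately the unit interval
#'
#' `method = "minmax"` maps each column's observed minimum to 0 and
#' maximum to 1 (a constant column maps to 0, with a warning);
#' `method = "isotropic"` divides each column by a supplied normalizer
#' (for example the isotropic symmetry-function normalizers). The returned
#' scaling record inverts the transformation exactly.
#'
#' @param features data frame / tibble of numeric features (>= 2 rows for
#'   minmax).
#' @param method `"minmax"` or `"isotropic"`.
#' @param normalizers named numeric vector of divisors (isotropic only).
#' @return a list with `features` (scaled tibble) and `scaling` (record
#'   usable by [unscale_features()]).
#' @export
scale_features <- function(features, method = c("minmax", "isotropic"),
                           normalizers = NULL) {
  method <- match.arg(method)
  features <- as_tibble(features)
  if (method == "minmax") {
    if (nrow(features) < 2) abort("minmax scaling needs >= 2 rows")
    lo <- vapply(features, min, numeric(1))
    hi <- vapply(features, max, numeric(1))
    const <- hi == lo
    if (any(const)) {
      warn(paste0("constant column(s) mapped to 0: ",
                  paste(names(features)[const], collapse = ", ")))
    }
    span <- ifelse(const, 1, hi - lo)
    scaled <- as_tibble(setNames(lapply(seq_along(features), function(j) {
      (features[[j]] - lo[j]) / span[j]
    }), names(features)))
    rec <- list(method = "minmax", min = lo, span = span,
                names = names(features))
  } else {
    if (is.null(normalizers)) abort("isotropic scaling needs normalizers")
    normalizers <- normalizers[names(features)]
    if (anyNA(normalizers)) abort("normalizer missing for some feature")
    scaled <- as_tibble(setNames(lapply(seq_along(features), function(j) {
      features[[j]] / normalizers[j]
    }), names(features)))
    rec <- list(method = "isotropic", divisor = normalizers,
                names = names(features))
  }
  list(features = scaled, scaling = rec)
}

#' @rdname scale_features
#' @param scaled scaled feature tibble.
#' @param scaling scaling record returned by [scale_features()].
#' @export
unscale_features <- function(scaled, scaling) {
  scaled <- as_tibble(scaled)
  if (scaling$method == "minmax") {
    as_tibble(setNames(lapply(seq_along(scaled), function(j) {
      scaled[[j]] * scaling$span[j] + scaling$min[j]
    }), names(scaled)))
  } else {
    as_tibble(setNames(lapply(seq_along(scaled), function(j) {
      scaled[[j]] * scaling$divisor[j]
    }), names(scaled)))
  }
}

identity_features <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}
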