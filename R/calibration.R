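# Thermodynamic calibrations: Flory-Huggins chi from demixed slabs and the
# chi-vs-excess-repulsion slope lambda; equation-of-state alpha; elastic
# fits; Gaussian bond/angle distribution fits.

#' Flory-Huggins chi from a demixed two-phase density profile
#'
#' For a lattice-fluid binary mixture that has demixed into an A-rich and a
#' B-rich slab, the minority volume fraction phi in the homogeneous interior
#' determines the chi-parameter through
#' `chi = ln[(1 - phi)/phi] / (1 - 2 phi)`.
#' The two interfaces are located where the A fraction crosses 0.5; bins
#' within `d_excl` of either interface are excluded and phi is the mean
#' minority fraction over the remaining slab interiors.
#'
#' @param profile A `dpd_profile` of a two-type (A/B) system along z.
#' @param d_excl Exclusion distance from each interface, in r0.
#' @return chi, with attributes `phi` and `n_bins_used`; `NA` (with a
#'   warning) if the system has not demixed.
#' @export
#' @examples
#' chi_for_phi(0.2) # ~2.31
chi_from_profile <- function(profile, d_excl = 2) {
  fA <- profile$fraction[1, ]
  z <- profile$centers
  Lz <- length(z) * profile$bin_width
  s <- sign(fA - 0.5)
  if (all(s >= 0) || all(s <= 0) || max(abs(fA - 0.5)) < 0.05) {
    warning("no demixing detected: chi undefined")
    return(NA_real_)
  }
  nb <- length(z)
  nxt <- c(2:nb, 1)
  cross <- which(s != s[nxt])
  # interface positions by linear interpolation on the (cyclic) crossing bins
  ifaces <- vapply(cross, function(b) {
    b2 <- if (b == nb) 1 else b + 1
    f1 <- fA[b]; f2 <- fA[b2]
    frac <- (0.5 - f1) / (f2 - f1)
    (z[b] + frac * profile$bin_width) %% Lz
  }, numeric(1))
  cyc_dist <- function(a, b) {
    d <- abs(a - b) %% Lz
    pmin(d, Lz - d)
  }
  dist_if <- vapply(z, function(zz) min(cyc_dist(zz, ifaces)), numeric(1))
  keep <- dist_if > d_excl
  if (!any(keep)) {
    warning("no homogeneous interior bins outside the interface exclusion zone")
    return(NA_real_)
  }
  phi <- mean(pmin(fA[keep], 1 - fA[keep]))
  chi <- chi_for_phi(phi)
  attr(chi, "phi") <- phi
  attr(chi, "n_bins_used") <- sum(keep)
  chi
}

#' @rdname chi_from_profile
#' @param phi Minority volume fraction in (0, 0.5].
#' @export
chi_for_phi <- function(phi) {
  stopifnot(all(phi > 0), all(phi <= 0.5))
  ifelse(abs(phi - 0.5) < 1e-10, 2, log((1 - phi) / phi) / (1 - 2 * phi))
}

# inverse of chi_for_phi on (0, 0.5); used by tests and synthetic fixtures
phi_for_chi <- function(chi) {
  vapply(chi, function(x) {
    if (x <= 2) return(0.5)
    uniroot(function(p) chi_for_phi(p) - x, c(1e-12, 0.5 - 1e-12),
            tol = 1e-14)$root
  }, numeric(1))
}

#' Fit the chi versus excess-repulsion slope lambda
#'
#' Zero-intercept (weighted) least squares of `chi = lambda * delta_a`.
#' Points whose chi is missing or at/below the critical value 2 (not
#' demixed) are excluded with a warning.
#'
#' @param deltas Excess repulsions `a_AB - a_AA` in kBT/r0.
#' @param chis Measured chi values.
#' @param weights Optional weights for the fit.
#' @return List with `lambda`, `se`, and the points `used`.
#' @export
fit_lambda <- function(deltas, chis, weights = NULL) {
  stopifnot(length(deltas) == length(chis))
  ok <- is.finite(chis) & chis > 2
  if (!all(ok)) {
    warning(sprintf("excluding %d non-demixed point(s) from the lambda fit",
                    sum(!ok)))
  }
  if (sum(ok) < 1) stop("no demixed points to fit")
  d <- deltas[ok]; ch <- as.numeric(chis[ok])
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  fit <- lm(ch ~ 0 + d, weights = w)
  # exact synthetic input gives a residual-free fit; the se is then 0
  list(lambda = unname(coef(fit)[1]),
       se = unname(suppressWarnings(sqrt(diag(vcov(fit))))[1]),
       used = data.frame(delta_a = d, chi = ch))
}

#' Fit the equation-of-state proportionality constant alpha
#'
#' The DPD fluid obeys `P = rho T + alpha a rho^2` at moderate-to-high
#' density; alpha links the repulsion strength to the dimensionless
#' compressibility via `k^-1 = 1 + 2 alpha a rho / kBT`.
#'
#' @param samples Data frame with columns `a`, `rho`, `P` (and optionally
#'   `temperature`, default 1).
#' @return List with `alpha`, `se`, and a `k_inv(a, rho)` function also
#'   reporting `k_inv / Nm`.
#' @export
fit_compressibility_alpha <- function(samples) {
  stopifnot(nrow(samples) >= 1)
  temp <- if (!is.null(samples$temperature)) samples$temperature else 1
  y <- samples$P - samples$rho * temp
  x <- samples$a * samples$rho^2
  if (all(x == 0)) stop("singular design: all repulsions zero")
  fit <- lm(y ~ 0 + x)
  alpha <- unname(coef(fit)[1])
  list(alpha = alpha,
       se = unname(suppressWarnings(sqrt(diag(vcov(fit))))[1]),
       k_inv = function(a, rho, temperature = 1, Nm = 4) {
         k <- 1 + 2 * alpha * a * rho / temperature
         list(k_inv = k, k_inv_per_molecule = k / Nm)
       })
}

#' Fit area compressibility and tensionless area from a tension scan
#'
#' Near the tensionless state the membrane tension is linear in the
#' projected area per lipid: `Sigma = K_A (a_prj - a0) / a0`. Points with
#' `|Sigma|` beyond `window` are dropped; if the retained tensions do not
#' change sign the fit extrapolates (warning).
#'
#' @param a_prj Projected areas per lipid, r0^2.
#' @param Sigma Measured tensions, kBT/r0^2.
#' @param window Half-width of the near-tensionless window, kBT/r0^2.
#' @return List with `K_A`, `a0`, standard errors, residuals and the points
#'   used.
#' @export
fit_area_compressibility <- function(a_prj, Sigma, window = 3) {
  stopifnot(length(a_prj) == length(Sigma), length(a_prj) >= 3)
  keep <- abs(Sigma) <= window
  if (sum(keep) < 3) keep <- rank(abs(Sigma)) <= 3
  if (min(Sigma[keep]) > 0 || max(Sigma[keep]) < 0) {
    warning("no sign change in Sigma within the window: extrapolating a0")
  }
  x <- a_prj[keep]; y <- Sigma[keep]
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  a0 <- -icpt / slope
  K_A <- slope * a0
  list(K_A = K_A, a0 = a0,
       residuals = unname(stats::residuals(fit)),
       used = data.frame(a_prj = x, Sigma = y))
}

#' Bending rigidity from area compressibility and thickness
#'
#' `kappa = K_A l_mem^2 / 48`, the polymer-brush relation linking the
#' stretching modulus and membrane thickness to the bending modulus.
#'
#' @param K_A Area compressibility, kBT/r0^2.
#' @param l_mem Membrane thickness, r0.
#' @param units A [dpd_units()] object.
#' @return List with `kappa` (kBT) and `kappa_J` (joules).
#' @export
#' @examples
#' bending_rigidity(48, 1)$kappa # 1
bending_rigidity <- function(K_A, l_mem, units = dpd_units()) {
  stopifnot(K_A > 0, l_mem > 0)
  kappa <- K_A * l_mem^2 / 48
  list(kappa = kappa, kappa_J = to_physical(kappa, "energy", units))
}

#' Fit a Gaussian to a bond-length or angle distribution
#'
#' Fits `P(x) = A / (w sqrt(pi/2)) exp(-2 (x - xc)^2 / w^2)` by nonlinear
#' least squares and returns the implied harmonic force constant
#' `K = 4 kBT / w^2` (the Boltzmann inversion of the Gaussian).
#'
#' @param x Samples (bond lengths or angles) or bin midpoints when `counts`
#'   is given.
#' @param counts Optional histogram counts matching `x`.
#' @param n_bins Number of histogram bins when raw samples are given.
#' @return List with `center`, `width`, `area`, `K` and the fitted model.
#' @export
fit_gaussian <- function(x, counts = NULL, n_bins = 50) {
  if (is.null(counts)) {
    h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
    mids <- h$mids
    counts <- h$counts
    bin_w <- diff(h$breaks)[1]
  } else {
    mids <- x
    bin_w <- if (length(mids) > 1) mids[2] - mids[1] else 1
  }
  df <- data.frame(mids = mids, y = counts / bin_w) # counts per unit x
  start <- list(A = sum(counts) * 1.0,
                xc = sum(mids * counts) / sum(counts),
                w = 2 * sqrt(sum(counts * (mids - sum(mids * counts) / sum(counts))^2) /
                               sum(counts)))
  fit <- minpack.lm::nlsLM(
    y ~ A / (w * sqrt(pi / 2)) * exp(-2 * (mids - xc)^2 / w^2),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  w <- abs(unname(cf["w"]))
  list(center = unname(cf["xc"]), width = w, area = unname(cf["A"]),
       K = 4 / w^2, fit = fit)
}

#' Calibrate the chi-repulsion slope from binary demixing simulations
#'
#' Runs the full demixing experiment: for each excess repulsion, build a
#' pre-separated A/B slab at density 3, equilibrate in the NVT ensemble,
#' accumulate the time-averaged composition profile during production,
#' convert the homogeneous-slab minority fraction to chi, and fit the
#' zero-intercept slope `chi = lambda * delta_a`.
#'
#' @param a_ii Like-bead repulsion (the mapping-number proxy: 100 for
#'   Nm = 4, 25 for Nm = 1).
#' @param deltas Excess repulsions to simulate.
#' @param box Box edge lengths in r0; the demixing axis is z.
#' @param steps_equil,steps_prod Equilibration and production steps.
#' @param n_bins Bins of the composition profile.
#' @param d_excl Interface exclusion distance for [chi_from_profile()].
#' @param dt Time step.
#' @param seed Integer seed.
#' @return List with `lambda`, `se`, and a `table` of per-delta results.
#' @export
calibrate_chi <- function(a_ii = 100, deltas = c(10, 13, 16),
                          box = c(5, 5, 20), steps_equil = 15000,
                          steps_prod = 35000, n_bins = 40, d_excl = 2,
                          dt = 0.02, seed = 1) {
  n_half <- round(DPD_RHO * prod(box) / 2)
  rows <- lapply(seq_along(deltas), function(k) {
    da <- deltas[k]
    ff <- binary_forcefield(a_ii, da)
    st <- build_binary_slab(n_half, n_half, box, seed = seed + k)
    eq <- run_dpd(st, ff, steps_equil, dt = dt, seed = seed + 100 * k,
                  sample_stride = 0L)
    pr <- run_dpd(eq$state, ff, steps_prod, dt = dt, seed = seed + 100 * k,
                  sample_stride = 10L, zhist_bins = n_bins)
    prof <- density_profile(pr$zhist)
    chi <- chi_from_profile(prof, d_excl = d_excl)
    data.frame(delta_a = da, chi = as.numeric(chi),
               phi = if (is.na(chi)) NA_real_ else attr(chi, "phi"))
  })
  tab <- do.call(rbind, rows)
  fit <- fit_lambda(tab$delta_a, tab$chi)
  list(lambda = fit$lambda, se = fit$se, table = tab)
}

#' Bulk pressure of the single-component DPD fluid
#'
#' Builds a water box at density 3, equilibrates, and averages the
#' diagonal virial pressure over production samples.
#'
#' @param a_ii Repulsion strength.
#' @param box Box edges in r0.
#' @param steps_equil,steps_prod Equilibration / production step counts.
#' @param dt Time step.
#' @param seed Integer seed.
#' @return List with `P`, `se`, `temperature` (mean kinetic), and `samples`.
#' @export
bulk_pressure <- function(a_ii = 100, box = c(10, 10, 10),
                          steps_equil = 10000, steps_prod = 10000,
                          dt = 0.02, seed = 1) {
  a <- matrix(a_ii, 1, 1, dimnames = list("W", "W"))
  ff <- forcefield(a)
  st <- build_bulk(box, seed = seed)
  eq <- run_dpd(st, ff, steps_equil, dt = dt, seed = seed, sample_stride = 0L)
  pr <- run_dpd(eq$state, ff, steps_prod, dt = dt, seed = seed,
                sample_stride = 10L)
  p <- (pr$samples$Pxx + pr$samples$Pyy + pr$samples$Pzz) / 3
  list(P = mean(p), se = sd(p) / sqrt(length(p)),
       temperature = mean(pr$samples$temperature), samples = pr$samples)
}

#' Equation-of-state scan over repulsion strengths
#'
#' Runs bulk NVT simulations at density 3 for each repulsion strength,
#' measures the mean virial pressure, and fits the proportionality
#' constant alpha of `P = rho T + alpha a rho^2`.
#'
#' @param a_values Repulsion strengths to scan.
#' @param box Box edges in r0.
#' @param steps_equil,steps_prod Step counts per run.
#' @param dt Time step.
#' @param seed Integer seed.
#' @return List with `alpha`, `se`, and the per-a `table`.
#' @export
eos_scan <- function(a_values = c(25, 50, 100), box = c(8, 8, 8),
                     steps_equil = 5000, steps_prod = 15000, dt = 0.02,
                     seed = 1) {
  rows <- lapply(seq_along(a_values), function(k) {
    bp <- bulk_pressure(a_values[k], box = box, steps_equil = steps_equil,
                        steps_prod = steps_prod, dt = dt, seed = seed + k)
    data.frame(a = a_values[k], rho = DPD_RHO, P = bp$P, P_se = bp$se,
               temperature = bp$temperature)
  })
  tab <- do.call(rbind, rows)
  fit <- fit_compressibility_alpha(tab)
  list(alpha = fit$alpha, se = fit$se, table = tab, k_inv = fit$k_inv)
}
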