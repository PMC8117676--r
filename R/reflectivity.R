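#' Specular reflectivity of a slab stack (Abeles matrix formalism)
#'
#' Exact specular neutron reflectivity of a stratified medium by the Abeles
#' transfer-matrix recursion, with Nevot-Croce Gaussian roughness factors
#' `exp(-2 k_n k_{n+1} sigma^2)` applied to each interfacial Fresnel
#' coefficient. Zero-thickness slabs are dropped before evaluation.
#'
#' @param stack a [layer_stack()]; slab SLDs are solvent-mixed per their
#'   solvent fractions before evaluation
#' @param q momentum-transfer grid, A^-1, all > 0
#' @return reflectivity R(q), dimensionless, in `[0, 1]`
#' @export
#' @examples
#' st <- layer_stack(2.07, list(), 6.36)
#' reflectivity_abeles(st, c(0.01, 0.05, 0.1))
reflectivity_abeles <- function(stack, q) {
  if (any(q <= 0)) stop("q must be positive")
  slabs <- Filter(function(s) s$thickness > 0, stack$slabs)
  eff <- vapply(slabs, function(s)
    (1 - s$solvent_fraction) * s$sld + s$solvent_fraction * stack$backing_sld,
    numeric(1))
  ieff <- vapply(slabs, function(s) (1 - s$solvent_fraction) * s$isld,
                 numeric(1))
  rho <- complex(real = c(stack$fronting_sld, eff, stack$backing_sld),
                 imaginary = c(0, ieff, 0)) * 1e-6
  d <- c(0, vapply(slabs, `[[`, numeric(1), "thickness"), 0)
  sig <- c(vapply(slabs, `[[`, numeric(1), "roughness"),
           stack$backing_roughness)
  if (length(slabs) == 0) sig <- stack$backing_roughness

  nq <- length(q)
  nm <- length(rho)                      # number of media
  k0 <- q / 2                           # wavevector in the fronting medium
  # k_j in each medium; complex sqrt handles evanescence below the edge
  k <- matrix(0i, nq, nm)
  for (j in seq_len(nm))
    k[, j] <- sqrt(as.complex(k0^2 - 4 * pi * (rho[j] - rho[1])))

  M11 <- rep(1 + 0i, nq); M12 <- rep(0i, nq)
  M21 <- rep(0i, nq); M22 <- rep(1 + 0i, nq)
  for (i in seq_len(nm - 1)) {
    ki <- k[, i]; kn <- k[, i + 1]
    r <- (ki - kn) / (ki + kn) * exp(-2 * ki * kn * sig[i]^2)
    beta <- if (i == 1) rep(0i, nq) else 1i * k[, i] * d[i]
    e <- exp(beta); einv <- exp(-beta)
    C11 <- e; C12 <- r * e; C21 <- r * einv; C22 <- einv
    N11 <- M11 * C11 + M12 * C21
    N12 <- M11 * C12 + M12 * C22
    N21 <- M21 * C11 + M22 * C21
    N22 <- M21 * C12 + M22 * C22
    M11 <- N11; M12 <- N12; M21 <- N21; M22 <- N22
  }
  R <- Mod(M21 / M11)^2
  pmin(R, 1)
}

# Gauss-Legendre nodes/weights for a normal-pdf weighted quadrature on
# +/- 3.5 sigma, renormalised so constants are preserved exactly.
resolution_kernel <- function(n = 17) {
  gl <- pracma::gaussLegendre(n, -3.5, 3.5)
  w <- gl$w * stats::dnorm(gl$x)
  list(x = gl$x, w = w / sum(w))
}

#' Gaussian resolution smearing of a reflectivity curve
#'
#' Convolves R(q) with a Gaussian resolution function of full width at half
#' maximum `dq` (per point), evaluated by fixed-order Gauss-Legendre
#' quadrature over +/- 3.5 standard deviations. The quadrature weights are
#' renormalised, so a constant curve is preserved exactly and the operation
#' is linear.
#'
#' Either supply a `model` function (exact re-evaluation at the quadrature
#' nodes, used during fitting) or a tabulated curve `R` (interpolated with a
#' natural spline).
#'
#' @param q evaluation grid, A^-1
#' @param R tabulated exact reflectivity on `q` (used when `model` is NULL)
#' @param dq_over_q constant relative resolution (fwhm / q); ignored when
#'   `dq` is given
#' @param dq per-point resolution fwhm, A^-1
#' @param model optional function `q -> R` evaluated exactly at the nodes
#' @param n quadrature order (default 17)
#' @return smeared reflectivity on `q`
#' @export
smear_gaussian <- function(q, R = NULL, dq_over_q = NULL, dq = NULL,
                           model = NULL, n = 17) {
  if (is.null(dq)) {
    if (is.null(dq_over_q)) stop("supply dq or dq_over_q")
    if (dq_over_q < 0) stop("dq_over_q must be >= 0")
    dq <- dq_over_q * q
  }
  if (all(dq == 0)) {
    if (!is.null(model)) return(model(q))
    return(R)
  }
  ker <- resolution_kernel(n)
  sigma <- dq / (2 * sqrt(2 * log(2)))
  # node matrix: each row the shifted q values for one curve point
  qn <- outer(sigma, ker$x) + q
  qn[qn <= 0] <- min(q[q > 0]) * 1e-3    # guard: keep nodes positive
  if (!is.null(model)) {
    Rn <- matrix(model(as.vector(qn)), nrow = length(q))
  } else {
    if (is.null(R)) stop("supply R or model")
    f <- stats::splinefun(q, R, method = "natural")
    Rn <- matrix(f(as.vector(qn)), nrow = length(q))
  }
  as.vector(Rn %*% ker$w)
}
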