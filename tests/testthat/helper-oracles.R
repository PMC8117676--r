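# Independent oracles used to cross-check the package implementations.

# Parratt bottom-up recursion for specular reflectivity (independent of the
# Abeles matrix code path). SLDs in 1e-6 A^-2, already solvent-mixed.
parratt_reflectivity <- function(fronting_sld, slab_slds, thicknesses,
                                 roughnesses, backing_sld,
                                 backing_roughness, q) {
  rho <- c(fronting_sld, slab_slds, backing_sld) * 1e-6
  d <- c(0, thicknesses, 0)
  sig <- c(roughnesses, backing_roughness)
  nm <- length(rho)
  vapply(q, function(qq) {
    k <- sqrt(as.complex((qq / 2)^2 - 4 * pi * (rho - rho[1])))
    r <- 0i
    for (i in seq(nm - 1, 1)) {
      Fr <- (k[i] - k[i + 1]) / (k[i] + k[i + 1]) *
        exp(-2 * k[i] * k[i + 1] * sig[i]^2)
      if (i == nm - 1) {
        r <- Fr
      } else {
        ph <- exp(2i * k[i + 1] * d[i + 1])
        r <- (Fr + r * ph) / (1 + Fr * r * ph)
      }
    }
    min(Mod(r)^2, 1)
  }, numeric(1))
}

# Closed-form Fresnel reflectivity of a bare interface.
fresnel_R <- function(q, rho_front, rho_back) {
  k0 <- q / 2
  k1 <- sqrt(as.complex(k0^2 - 4 * pi * (rho_back - rho_front) * 1e-6))
  Mod((k0 - k1) / (k0 + k1))^2
}

# Brute-force dense-grid Gaussian convolution of a model curve.
dense_smear <- function(q, model_fn, dq) {
  sigma <- dq / (2 * sqrt(2 * log(2)))
  vapply(seq_along(q), function(i) {
    if (sigma[i] == 0) return(model_fn(q[i]))
    x <- seq(-4 * sigma[i], 4 * sigma[i], length.out = 4001)
    qq <- pmax(q[i] + x, 1e-6)
    w <- dnorm(x, sd = sigma[i])
    sum(w * model_fn(qq)) / sum(w)
  }, numeric(1))
}

# Numeric body-of-revolution oracle for the circular (ellipticity = 1)
# core-shell disc: radial J0 integral and axial cosine integral evaluated by
# trapezoid, orientation average by fine Gauss-Legendre. Independent of the
# closed-form J1/sinc amplitudes.
circular_disc_intensity <- function(q, model, d2o_fraction, n_r = 600,
                                    n_z = 200, n_alpha = 200,
                                    materials = lipidscatter::default_materials()) {
  stopifnot(model$ellipticity == 1)
  sl <- disc_slds(model, d2o_fraction, materials)
  regions <- list(
    list(a = model$r_minor + model$d_belt,
         h = model$core_length / 2 + model$t_face,
         drho = sl$rim - sl$solvent),
    list(a = model$r_minor, h = model$core_length / 2 + model$t_face,
         drho = sl$face - sl$rim),
    list(a = model$r_minor, h = model$core_length / 2,
         drho = sl$core - sl$face))
  ga <- pracma::gaussLegendre(n_alpha, 0, pi / 2)
  wa <- ga$w * sin(ga$x); wa <- wa / sum(wa)
  Vo <- pi * regions[[1]]$a^2 * 2 * regions[[1]]$h
  trap <- function(y, x) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  vapply(q, function(qq) {
    Fa <- vapply(seq_along(ga$x), function(ia) {
      al <- ga$x[ia]
      qr <- qq * sin(al); qz <- qq * cos(al)
      sum(vapply(regions, function(g) {
        r <- seq(0, g$a, length.out = n_r)
        rad <- 2 * pi * trap(besselJ(pmax(qr * r, 1e-12), 0) * r, r)
        z <- seq(0, g$h, length.out = n_z)
        ax <- 2 * trap(cos(qz * z), z)
        g$drho * 1e-6 * rad * ax
      }, numeric(1)))
    }, numeric(1))
    1e8 * model$scale * sum(wa * Fa^2) / Vo
  }, numeric(1))
}
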