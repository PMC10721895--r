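#' Solution state for a CaCO3 mineralization experiment
#'
#' Describes the mixed solution (e.g. 5 mM CaCl2 + 5 mM NaHCO3, the standard
#' templating condition). Chloride and sodium counter-ions implied by the
#' salts are carried into the charge balance; pH is solved from charge
#' balance when not supplied.
#'
#' @param total_ca Total calcium, mol/L.
#' @param total_carbonate Total dissolved carbonate (all species), mol/L.
#' @param pH Optional fixed pH; solved from charge balance when `NULL`.
#' @param temperature Kelvin (constants are supplied at 25 C).
#' @return A `solution_state` list.
#' @export
solution_state <- function(total_ca = 5e-3, total_carbonate = 5e-3,
                           pH = NULL, temperature = 298.15) {
  if (total_ca < 0 || total_carbonate < 0) stop("totals must be >= 0.")
  if (!is.null(pH) && (pH <= 0 || pH >= 14)) stop("pH must lie in (0, 14).")
  structure(
    list(total_ca = total_ca, total_carbonate = total_carbonate, pH = pH,
         temperature = temperature,
         na = total_carbonate, # from NaHCO3
         cl = 2 * total_ca),   # from CaCl2
    class = "solution_state"
  )
}

#' Equilibrium constants for the carbonate system and CaCO3 phases
#'
#' Standard 25 C literature values bundled as defaults; each constant
#' carries a source annotation. Solubility products decrease in stability
#' order calcite > aragonite > vaterite > amorphous CaCO3 (ACC), i.e.
#' pKsp(calcite) > pKsp(aragonite) > pKsp(vaterite) > pKsp(ACC).
#'
#' @param pK1,pK2 Carbonic acid dissociation constants.
#' @param pKw Water ion product.
#' @param pKsp Named vector of solubility products for `calcite`,
#'   `aragonite`, `vaterite`, `ACC`.
#' @param source Provenance annotation.
#' @return A `phase_constants` list.
#' @export
phase_constants <- function(pK1 = 6.352, pK2 = 10.329, pKw = 13.997,
                            pKsp = c(calcite = 8.48, aragonite = 8.336,
                                     vaterite = 7.913, ACC = 6.40),
                            source = "standard 25 C values (Plummer & Busenberg 1982; Brecevic & Nielsen 1989 for ACC)") {
  need <- c("calcite", "aragonite", "vaterite", "ACC")
  if (!all(need %in% names(pKsp))) stop("pKsp needs calcite, aragonite, vaterite, ACC.")
  if (!(pKsp["calcite"] > pKsp["aragonite"] &&
        pKsp["aragonite"] > pKsp["vaterite"] &&
        pKsp["vaterite"] > pKsp["ACC"])) {
    stop("pKsp must decrease in the order calcite > aragonite > vaterite > ACC.")
  }
  structure(list(pK1 = pK1, pK2 = pK2, pKw = pKw, pKsp = pKsp, source = source),
            class = "phase_constants")
}

# Davies activity coefficient for charge z at ionic strength I (mol/L),
# valid to ~0.1 M; A = 0.511 at 25 C.
#' @noRd
davies_gamma <- function(z, I, A = 0.511) {
  if (I <= 0) return(rep(1, length(z)))
  sqI <- sqrt(I)
  10^(-A * z^2 * (sqI / (1 + sqI) - 0.3 * I))
}

#' Carbonate speciation with Davies activity corrections
#'
#' Solves the closed-system carbonate equilibria (no CO2 exchange with the
#' atmosphere) for the free-ion activities. When pH is not given it is
#' solved from the full charge balance (Na+, Ca2+, H+, Cl-, HCO3-, CO32-,
#' OH-) by root bracketing on (0, 14); activity coefficients are iterated
#' to self-consistency. Ion pairing is neglected (free Ca = total Ca).
#'
#' @param state A [solution_state()].
#' @param constants A [phase_constants()].
#' @return A list with `activities` (named: `Ca`, `CO3`, `HCO3`, `H`, `OH`),
#'   `concentrations`, `pH`, `ionic_strength`, `gamma` and
#'   `charge_balance_residual` (eq/L). When total carbonate is zero the CO3
#'   activity is 0 and `saturation_defined` is `FALSE`.
#' @examples
#' sp <- speciate(solution_state(5e-3, 5e-3))
#' sp$pH
#' @export
speciate <- function(state, constants = phase_constants()) {
  stopifnot(inherits(state, "solution_state"))
  K1 <- 10^(-constants$pK1); K2 <- 10^(-constants$pK2); Kw <- 10^(-constants$pKw)
  CT <- state$total_carbonate; CaT <- state$total_ca

  solve_at_gamma <- function(g1, g2) {
    # activity-corrected speciation: {H} = activity of H+, concentrations
    # of carbonate species from conditional constants K' = K / gamma
    frac <- function(aH) {
      # conditional constants relating concentrations at fixed activities
      k1c <- K1 / g1 # {H}[HCO3-]/[H2CO3*]: gamma of HCO3-
      k2c <- K2 * g1 / g2
      denom <- 1 + k1c / aH + (k1c * k2c) / aH^2
      h2co3 <- CT / denom
      hco3 <- h2co3 * k1c / aH
      co3 <- hco3 * k2c / aH
      list(h2co3 = h2co3, hco3 = hco3, co3 = co3)
    }
    balance <- function(pH) {
      aH <- 10^(-pH)
      f <- frac(aH)
      oh <- Kw / aH / g1
      h <- aH / g1
      state$na + 2 * CaT + h - state$cl - f$hco3 - 2 * f$co3 - oh
    }
    if (!is.null(state$pH)) {
      pH <- state$pH
    } else {
      lo <- 1e-6; hi <- 14 - 1e-6
      if (balance(lo) * balance(hi) > 0) stop("no charge-balance root in (0, 14).")
      pH <- stats::uniroot(balance, c(lo, hi), tol = 1e-14)$root
    }
    aH <- 10^(-pH)
    f <- frac(aH)
    list(pH = pH, f = f, aH = aH,
         residual = if (is.null(state$pH)) balance(pH) else NA_real_)
  }

  g1 <- 1; g2 <- 1; I <- 0
  for (it in 1:50) {
    sol <- solve_at_gamma(g1, g2)
    conc <- c(Ca = CaT, CO3 = sol$f$co3, HCO3 = sol$f$hco3,
              H = sol$aH / g1, OH = (10^(-constants$pKw)) / sol$aH / g1,
              Na = state$na, Cl = state$cl)
    z <- c(Ca = 2, CO3 = -2, HCO3 = -1, H = 1, OH = -1, Na = 1, Cl = -1)
    I_new <- 0.5 * sum(conc * z^2)
    g1_new <- davies_gamma(1, I_new); g2_new <- davies_gamma(2, I_new)
    conv <- abs(I_new - I) < 1e-12
    I <- I_new; g1 <- g1_new; g2 <- g2_new
    if (conv) break
  }
  sol <- solve_at_gamma(g1, g2)
  conc <- c(Ca = CaT, CO3 = sol$f$co3, HCO3 = sol$f$hco3,
            H = sol$aH / g1, OH = (10^(-constants$pKw)) / sol$aH / g1)
  act <- c(Ca = CaT * g2, CO3 = sol$f$co3 * g2, HCO3 = sol$f$hco3 * g1,
           H = sol$aH, OH = (10^(-constants$pKw)) / sol$aH)
  list(
    activities = act,
    concentrations = conc,
    pH = sol$pH,
    ionic_strength = I,
    gamma = c(z1 = g1, z2 = g2),
    charge_balance_residual = sol$residual,
    saturation_defined = CT > 0 && CaT > 0
  )
}

#' Saturation index of a CaCO3 phase
#'
#' SI = log10(a_Ca * a_CO3) + pKsp(phase); SI > 0 means the solution is
#' supersaturated with respect to that phase.
#'
#' @param speciation Output of [speciate()] (or a list with an `activities`
#'   element containing `Ca` and `CO3`).
#' @param phase One of `"calcite"`, `"aragonite"`, `"vaterite"`, `"ACC"`.
#' @param constants A [phase_constants()].
#' @return SI (numeric). A zero activity gives `-Inf` with attribute
#'   `zero_activity = TRUE`.
#' @examples
#' sp <- speciate(solution_state(5e-3, 5e-3))
#' saturation_index(sp, "calcite") > 0
#' @export
saturation_index <- function(speciation, phase, constants = phase_constants()) {
  phase <- match.arg(phase, names(constants$pKsp))
  a <- speciation$activities
  iap <- unname(a["Ca"] * a["CO3"])
  if (iap <= 0) {
    out <- -Inf
    attr(out, "zero_activity") <- TRUE
    return(out)
  }
  unname(log10(iap) + constants$pKsp[phase])
}

#' Classical nucleation theory parameters
#'
#' @param gamma Interfacial free energy, J/m^2.
#' @param v Molecular volume of the solid, m^3 (calcite: 6.13e-29 m^3).
#' @param S Supersaturation ratio IAP/Ksp (> 0).
#' @param temperature Kelvin.
#' @param theta Contact angle on the template, radians (pi = no template
#'   benefit).
#' @return A `cnt_params` list.
#' @export
cnt_params <- function(gamma = 0.12, v = 6.13e-29, S = 10,
                       temperature = 298.15, theta = pi) {
  if (gamma <= 0) stop("`gamma` must be > 0.")
  if (S <= 0) stop("`S` must be > 0.")
  if (theta < 0 || theta > pi) stop("`theta` must lie in [0, pi].")
  structure(list(gamma = gamma, v = v, S = S, temperature = temperature,
                 theta = theta), class = "cnt_params")
}

#' Classical nucleation barrier and free-energy profile
#'
#' Homogeneous spherical-nucleus CNT:
#' r* = 2 gamma v / (kT ln S), dG* = 16 pi gamma^3 v^2 / (3 (kT ln S)^2),
#' dG(r) = -(4/3) pi r^3 kT ln S / v + 4 pi r^2 gamma. A template reduces
#' the barrier by the spherical-cap factor of [heterogeneous_factor()];
#' the critical radius of curvature is unchanged by the template while the
#' cap (nucleus) volume shrinks, so both are reported.
#'
#' @param params A [cnt_params()].
#' @param n_profile Number of radii in the returned profile (0 to 2 r*).
#' @return A `cnt_barrier` list: `r_star` (m), `dG_star` (J, homogeneous),
#'   `dG_star_het` (J, scaled by f(theta)), `f_theta`, `cap_volume` (m^3),
#'   `sphere_volume` (m^3) and `profile` (tibble `r`, `dG`). If S <= 1 a
#'   no-barrier condition is signalled via `barrier_finite = FALSE` with
#'   infinite `r_star`.
#' @examples
#' b <- cnt_barrier(cnt_params(gamma = 0.1, S = 4))
#' b$r_star
#' @export
cnt_barrier <- function(params, n_profile = 200L) {
  stopifnot(inherits(params, "cnt_params"))
  kB <- 1.380649e-23
  kT <- kB * params$temperature
  lnS <- log(params$S)
  f <- heterogeneous_factor(params$theta)
  if (lnS <= 0) {
    return(structure(
      list(r_star = Inf, dG_star = Inf, dG_star_het = Inf, f_theta = f,
           cap_volume = Inf, sphere_volume = Inf,
           profile = tibble::tibble(r = numeric(), dG = numeric()),
           barrier_finite = FALSE),
      class = "cnt_barrier"
    ))
  }
  drive <- kT * lnS / params$v # J/m^3
  r_star <- 2 * params$gamma / drive
  dG_star <- 16 * pi * params$gamma^3 / (3 * drive^2)
  dG <- function(r) -(4 / 3) * pi * r^3 * drive + 4 * pi * r^2 * params$gamma
  rs <- seq(0, 2 * r_star, length.out = n_profile)
  theta <- params$theta
  cap_volume <- (4 / 3) * pi * r_star^3 * f
  structure(
    list(r_star = r_star, dG_star = dG_star, dG_star_het = f * dG_star,
         f_theta = f, cap_volume = cap_volume,
         sphere_volume = (4 / 3) * pi * r_star^3,
         profile = tibble::tibble(r = rs, dG = dG(rs)),
         dG_fun = dG, barrier_finite = TRUE),
    class = "cnt_barrier"
  )
}

#' Spherical-cap heterogeneous nucleation factor
#'
#' f(theta) = (2 + cos theta)(1 - cos theta)^2 / 4, the factor by which a
#' template with contact angle theta reduces the homogeneous nucleation
#' barrier: f(0) = 0 (perfect wetting), f(pi/2) = 1/2, f(pi) = 1 (no
#' template benefit).
#'
#' @param theta Contact angle, radians, in [0, pi].
#' @return f in [0, 1].
#' @examples
#' heterogeneous_factor(pi / 2) # 0.5
#' @export
heterogeneous_factor <- function(theta) {
  if (any(theta < 0 | theta > pi)) stop("`theta` must lie in [0, pi].")
  (2 + cos(theta)) * (1 - cos(theta))^2 / 4
}
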