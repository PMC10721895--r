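#' Particle number density from molar concentration
#'
#' @param concentration mol/L (>= 0).
#' @return Particles per mL: `concentration * N_A / 1000`.
#' @examples
#' number_density(1.08e-6) # ~6.5e14, the monomer density at 1.08 uM
#' @export
number_density <- function(concentration) {
  if (any(concentration < 0)) stop("concentration must be >= 0.")
  concentration * 6.02214076e23 / 1000
}

#' Circular dichroism record for mean-residue-ellipticity conversion
#'
#' @param raw_signal Raw CD signal, millidegrees.
#' @param n_residues Number of residues (>= 1).
#' @param conc_molar Protein concentration, mol/L (> 0).
#' @param path_cm Cuvette path length, cm (default 0.1, a 1 mm cuvette).
#' @return A `cd_record` list.
#' @export
cd_record <- function(raw_signal, n_residues, conc_molar, path_cm = 0.1) {
  if (n_residues < 1) stop("`n_residues` must be >= 1.")
  if (conc_molar <= 0) stop("`conc_molar` must be > 0.")
  if (path_cm <= 0) stop("`path_cm` must be > 0.")
  structure(list(raw_signal = raw_signal, n_residues = n_residues,
                 conc_molar = conc_molar, path_cm = path_cm),
            class = "cd_record")
}

#' Convert raw CD signal to mean residue ellipticity
#'
#' MRE = raw / (N x C x L x 10), in deg cm^2 dmol^-1, with N the residue
#' count, C the molar concentration and L the path length in cm.
#'
#' @param rec A [cd_record()].
#' @return Mean residue ellipticity (vectorized over `raw_signal`).
#' @export
mre_convert <- function(rec) {
  stopifnot(inherits(rec, "cd_record"))
  rec$raw_signal / (rec$n_residues * rec$conc_molar * rec$path_cm * 10)
}

#' Particle-size sample
#'
#' @param sizes Measured particle diameters, nm (> 0).
#' @param label Sample label.
#' @return A `particle_sample` list with `sizes`, `label`, `n`.
#' @export
particle_sample <- function(sizes, label = "sample") {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 1) stop("empty particle sample.")
  if (any(sizes <= 0)) stop("particle sizes must be > 0.")
  structure(list(sizes = sizes, label = label, n = length(sizes)),
            class = "particle_sample")
}

#' Mean, standard deviation and count of a particle sample
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator),
#' reported to 0.1 nm as in figure captions.
#'
#' @param sample A [particle_sample()].
#' @return A tibble with `label`, `mean_nm`, `sd_nm`, `n` and unrounded
#'   `mean_raw`, `sd_raw`.
#' @examples
#' particle_stats(particle_sample(c(5, 5, 5)))
#' @export
particle_stats <- function(sample) {
  stopifnot(inherits(sample, "particle_sample"))
  m <- mean(sample$sizes)
  s <- if (sample$n > 1) stats::sd(sample$sizes) else 0
  tibble::tibble(label = sample$label, mean_nm = round(m, 1),
                 sd_nm = round(s, 1), n = sample$n,
                 mean_raw = m, sd_raw = s)
}

#' Published template-size series (packaged summary fixture)
#'
#' Summary statistics of the particle-size distributions measured for the
#' FD31 length series, together with the template interface areas of the
#' 3-, 6- and 9-repeat variants. These are packaged summary numbers (mean,
#' SD, n per variant); raw per-particle measurements are not available and
#' are not synthesized.
#'
#' @return A tibble with `template`, `n_repeats`, `interface_nm` (short and
#'   long extents), `area_nm2`, `n`, `mean_size_nm`, `sd_size_nm`.
#' @export
template_size_series <- function() {
  tibble::tibble(
    template = c("FD31-Rep3", "FD31", "FD31-Rep9"),
    n_repeats = c(3L, 6L, 9L),
    short_nm = c(5, 5, 5),
    long_nm = c(5, 8, 11),
    area_nm2 = c(25, 40, 55),
    n = c(172L, 150L, 147L),
    mean_size_nm = c(9.1, 5.5, 4.7),
    sd_size_nm = c(2.9, 0.9, 0.8)
  )
}

#' Fit inverse particle surface area against template area
#'
#' Least-squares fit of 1/(pi S^2) (spherical surface-area convention for a
#' particle of diameter S; set `convention = "S2"` for the plain S^2
#' convention) versus template interface area, testing the linear scaling
#' of inverse particle area with template size.
#'
#' @param data A data frame with columns `area_nm2` (template interface
#'   area) and `mean_size_nm` (mean particle diameter), e.g.
#'   [template_size_series()].
#' @param convention `"piS2"` (default) or `"S2"`.
#' @return A `scaling_fit` object wrapping the `lm` fit, with `slope`,
#'   `intercept`, `correlation` and the transformed `data`.
#' @examples
#' fit <- scaling_fit(template_size_series())
#' fit$slope > 0
#' @export
scaling_fit <- function(data, convention = c("piS2", "S2")) {
  convention <- match.arg(convention)
  stopifnot(all(c("area_nm2", "mean_size_nm") %in% names(data)))
  if (length(unique(data$area_nm2)) < 2) {
    stop("degenerate fit: need >= 2 distinct template areas.")
  }
  y <- if (convention == "piS2") 1 / (pi * data$mean_size_nm^2) else 1 / data$mean_size_nm^2
  d <- tibble::tibble(area_nm2 = data$area_nm2, inv_particle_area = y)
  fit <- stats::lm(inv_particle_area ~ area_nm2, data = d)
  structure(
    list(fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         correlation = stats::cor(d$area_nm2, d$inv_particle_area),
         convention = convention,
         data = d),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> 1/(%s) ~ template area: slope %.3g, intercept %.3g, r = %.3f\n",
    if (x$convention == "piS2") "pi S^2" else "S^2",
    x$slope, x$intercept, x$correlation
  ))
  invisible(x)
}
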