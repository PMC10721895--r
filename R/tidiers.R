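#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.flatten_result <- function(x, ...) x$grid

#' @export
glance.flatten_result <- function(x, ...) {
  tibble::tibble(
    selected_d_rep = x$selected_d_rep,
    score = min(x$grid$score),
    n_candidates = nrow(x$grid),
    selection_window = x$selection_window,
    n_in_window = length(x$in_window),
    seed = x$seed
  )
}

#' @export
tidy.dock_result <- function(x, ...) x$trajectory

#' @export
glance.dock_result <- function(x, ...) {
  tibble::tibble(
    e_complex = x$e_complex,
    e_start = x$e_start,
    baseline_median = stats::median(x$baseline),
    baseline_n = length(x$baseline),
    e_binding = x$e_binding,
    seed = x$seed
  )
}

#' @export
tidy.scaling_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    correlation = x$correlation,
    r.squared = summary(x$fit)$r.squared,
    convention = x$convention
  )
}

#' @export
tidy.cnt_barrier <- function(x, ...) x$profile

#' @export
glance.cnt_barrier <- function(x, ...) {
  tibble::tibble(
    r_star_m = x$r_star,
    dG_star_J = x$dG_star,
    dG_star_het_J = x$dG_star_het,
    f_theta = x$f_theta,
    barrier_finite = x$barrier_finite
  )
}

#' @export
tidy.match_result <- function(x, ...) {
  if (!is.null(x$rows)) return(x$rows)
  tibble::tibble(rotation = x$rotation,
                 matched_fraction = x$matched_fraction,
                 mismatch_strain = x$mismatch_strain)
}
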