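#' Packaged design fixtures
#'
#' Builds the idealized backbone model and surface array for one of the
#' packaged designs and variants, and asserts at load time that the array
#' composition reproduces the published totals (36/18/54 carboxylates for
#' FD31 at 6/3/9 repeats; 24 Asp + 18 Glu for DHR49-Neg; 18 Gln, 24 Asp and
#' 13 Lys substitutions for the FD31 surface-chemistry variants). FD15's
#' slot count is not published; its totals are flagged unverified.
#'
#' @param name One of `"FD15"`, `"FD31"`, `"FD31-Rep3"`, `"FD31-Rep9"`,
#'   `"FD31-Gln-Checker"`, `"FD31-Asp"`, `"FD31-Lys-Checker"`,
#'   `"DHR49-Neg"`.
#' @return A list with `name`, `model` (`backbone_model`), `array`
#'   (`surface_array`), `topology` and `d_rep` (Angstrom).
#' @examples
#' fx <- load_fixture("FD31")
#' nrow(fx$array) # 36
#' @export
load_fixture <- function(name) {
  known <- c("FD15", "FD31", "FD31-Rep3", "FD31-Rep9", "FD31-Gln-Checker",
             "FD31-Asp", "FD31-Lys-Checker", "DHR49-Neg")
  if (!name %in% known) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(known, collapse = ", ")))
  }
  base <- switch(name,
    "FD15" = "FD15",
    "DHR49-Neg" = "DHR49-Neg",
    "FD31")
  defs <- design_topologies()[[base]]
  topo <- defs$topology
  n_rep <- switch(name, "FD31-Rep3" = 3L, "FD31-Rep9" = 9L, topo$n_repeats)

  model <- build_repeat_model(topo, d_rep = defs$d_rep)
  if (n_rep != topo$n_repeats) model <- resize_repeats(model, n_rep)
  array <- extract_surface_array(model)

  scheme <- switch(name,
    "FD31-Gln-Checker" = recoding_scheme("gln_checker", n_rep, defs$slots_per_repeat),
    "FD31-Asp" = recoding_scheme("asp_variant", n_rep, defs$slots_per_repeat),
    "FD31-Lys-Checker" = recoding_scheme("lys_checker", n_rep, defs$slots_per_repeat),
    NULL)
  if (!is.null(scheme)) array <- apply_recoding(array, scheme)

  check_fixture_composition(name, array)
  list(name = name, model = model, array = array, topology = topo,
       d_rep = defs$d_rep)
}

#' List the packaged fixtures and their expected compositions
#' @return A tibble with fixture names and composition summaries.
#' @export
list_fixtures <- function() {
  tibble::tibble(
    name = c("FD15", "FD31", "FD31-Rep3", "FD31-Rep9", "FD31-Gln-Checker",
             "FD31-Asp", "FD31-Lys-Checker", "DHR49-Neg"),
    positions = c(24L, 36L, 18L, 54L, 36L, 36L, 36L, 42L),
    summary = c("24 Glu (slot count unverified)", "36 Glu", "18 Glu",
                "54 Glu", "18 Glu + 18 Gln", "12 Glu + 24 Asp",
                "23 Glu + 13 Lys", "18 Glu + 24 Asp")
  )
}

#' @noRd
check_fixture_composition <- function(name, array) {
  comp <- composition(array)
  n_of <- function(res) {
    i <- which(comp$residue == res)
    if (length(i) == 0) 0L else comp$n[i]
  }
  ok <- switch(name,
    "FD31" = n_of("GLU") == 36L,
    "FD31-Rep3" = n_of("GLU") == 18L,
    "FD31-Rep9" = n_of("GLU") == 54L,
    "FD31-Gln-Checker" = n_of("GLU") == 18L && n_of("GLN") == 18L,
    "FD31-Asp" = n_of("ASP") == 24L && n_of("GLU") == 12L,
    "FD31-Lys-Checker" = n_of("LYS") == 13L && n_of("GLU") == 23L,
    "DHR49-Neg" = n_of("ASP") == 24L && n_of("GLU") == 18L,
    "FD15" = TRUE # slot count not published; not asserted
  )
  if (!isTRUE(ok)) {
    stop(sprintf("fixture '%s' composition does not reproduce the published counts", name))
  }
  invisible(TRUE)
}
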