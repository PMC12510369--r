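# Elemental and charge balance for aerobic microbial growth on a carbohydrate
# with ammonium as nitrogen source:
#
#   1 substrate + a NH4+ + b O2 -> c biomass + d CO2 + e H2O + f H+
#
# Given the biomass yield (C-mol biomass per mol substrate) the system is
# closed-form: N balance gives a, C balance gives d, charge balance gives
# f = a (every ammonium taken up leaves one proton behind, which is what
# acidifies an unbuffered culture), H balance gives e, O balance gives b.
# The degree-of-reduction balance (gamma = 4C + H - 2O - 3N, the
# ammonium-as-N-source convention) is redundant and is used as a consistency
# check on the solve.

#' Parse an elemental formula string
#'
#' Parses formulas like `"C6H12O6"` or the C-mol biomass composition
#' `"CH1.8N0.2O0.5"` into atom counts. Only C, H, O and N are supported;
#' counts may be non-integer (biomass compositions are per C-mol). A trailing
#' `+` or `-` sets a unit charge.
#'
#' @param x Formula string.
#' @return A list of class `elemental_formula` with fields `c`, `h`, `o`,
#'   `n`, `charge`.
#' @export
parse_elemental_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  charge <- 0
  if (grepl("[+-]$", x)) {
    charge <- if (endsWith(x, "+")) 1 else -1
    x <- substr(x, 1L, nchar(x) - 1L)
  }
  m <- gregexpr("([CHON])([0-9]*\\.?[0-9]*)", x)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula '", x, "' (elements C, H, O, N only)")
  }
  tokens <- regmatches(x, gregexpr("([CHON])([0-9]*\\.?[0-9]*)", x))[[1]]
  counts <- c(c = 0, h = 0, o = 0, n = 0)
  for (tok in tokens) {
    el <- tolower(substr(tok, 1L, 1L))
    num <- substr(tok, 2L, nchar(tok))
    counts[el] <- counts[el] + if (nzchar(num)) as.numeric(num) else 1
  }
  if (all(counts == 0)) stop("formula '", x, "' has no atoms")
  structure(as.list(c(counts, charge = charge)), class = "elemental_formula")
}

as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) x else parse_elemental_formula(x)
}

#' Degree of reduction of a CHON formula
#'
#' Electrons available per formula unit under the ammonium-as-nitrogen-source
#' convention: `gamma = 4C + H - 2O - 3N`.
#'
#' @param formula An `elemental_formula` or formula string.
#' @return Numeric degree of reduction.
#' @export
degree_of_reduction <- function(formula) {
  f <- as_formula(formula)
  4 * f$c + f$h - 2 * f$o - 3 * f$n
}

#' Solve the aerobic growth stoichiometry
#'
#' Solves `1 substrate + a NH4+ + b O2 -> c biomass + d CO2 + e H2O + f H+`
#' for the coefficients a, b, c, d, e, f given the substrate formula, the
#' biomass elemental composition and the biomass yield in C-mol per mol
#' substrate. The yield is an explicit input; it is never inferred.
#'
#' @param substrate Substrate formula (string or `elemental_formula`), e.g.
#'   `"C6H12O6"`.
#' @param biomass Biomass composition, typically per C-mol, e.g.
#'   `"CH1.8N0.2O0.5"`.
#' @param biomass_yield_c Biomass yield in C-mol biomass per mol substrate;
#'   must lie in `[0, substrate carbon]`.
#' @return An object of class `growth_stoichiometry`: a list with
#'   `substrate_coeff` (1), `nh4_coeff`, `o2_coeff`, `biomass_coeff`,
#'   `co2_coeff`, `h2o_coeff`, `hplus_coeff`, the two formulas, and
#'   `residuals` (closure errors of the C, H, O, N, charge and
#'   degree-of-reduction balances; all ~0 by construction).
#' @details A solved coefficient that comes out negative (an infeasible
#'   yield, e.g. more biomass hydrogen than the substrate plus ammonium can
#'   supply) is an error. With yield 0 the solve reduces to complete
#'   combustion.
#' @export
solve_growth_stoichiometry <- function(substrate, biomass, biomass_yield_c) {
  s <- as_formula(substrate)
  x <- as_formula(biomass)
  stopifnot(s$c > 0, x$c > 0)
  if (biomass_yield_c < 0 || biomass_yield_c > s$c) {
    stop("biomass_yield_c must lie in [0, ", s$c, "] C-mol per mol substrate")
  }
  cc <- biomass_yield_c / x$c          # mol biomass formula units
  a <- cc * x$n - s$n                  # N balance (NH4+ carries one N)
  d <- s$c - cc * x$c                  # C balance
  f <- a + s$charge                    # charge balance (NH4+ in, H+ out)
  e <- (s$h + 4 * a - cc * x$h - f) / 2   # H balance
  b <- (cc * x$o + 2 * d + e - s$o) / 2   # O balance
  coefs <- c(nh4 = a, o2 = b, biomass = cc, co2 = d, h2o = e, hplus = f)
  if (any(coefs < -1e-12)) {
    stop("infeasible yield: negative coefficient(s) ",
         paste(names(coefs)[coefs < -1e-12], collapse = ", "))
  }
  residuals <- c(
    carbon = s$c - (cc * x$c + d),
    hydrogen = s$h + 4 * a - (cc * x$h + 2 * e + f),
    oxygen = s$o + 2 * b - (cc * x$o + 2 * d + e),
    nitrogen = s$n + a - cc * x$n,
    charge = s$charge + a - f,
    electron = degree_of_reduction(s) -
      (cc * degree_of_reduction(x) + 4 * b))
  structure(list(substrate_coeff = 1, nh4_coeff = a, o2_coeff = b,
                 biomass_coeff = cc, co2_coeff = d, h2o_coeff = e,
                 hplus_coeff = f, substrate_formula = s, biomass_formula = x,
                 biomass_yield_c = biomass_yield_c, residuals = residuals),
            class = "growth_stoichiometry")
}

#' Protons released per mole of substrate consumed
#'
#' The H+ coefficient of a solved growth stoichiometry. With ammonium as the
#' sole nitrogen source this equals the ammonium coefficient by charge
#' balance, which is why ammonium uptake acidifies an unbuffered culture.
#'
#' @param stoich A `growth_stoichiometry` from [solve_growth_stoichiometry()].
#' @return Numeric, mol H+ per mol substrate.
#' @export
protons_per_substrate <- function(stoich) {
  stopifnot(inherits(stoich, "growth_stoichiometry"))
  stoich$hplus_coeff
}

format_chon <- function(f) {
  piece <- function(sym, v) {
    if (v == 0) "" else if (v == 1) sym else paste0(sym, signif(v, 6))
  }
  paste0(piece("C", f$c), piece("H", f$h), piece("N", f$n), piece("O", f$o))
}

#' @export
print.growth_stoichiometry <- function(x, digits = 3, ...) {
  r <- function(v) format(round(v, digits))
  cat(sprintf("1 %s + %s NH4+ + %s O2 -> %s %s + %s CO2 + %s H2O + %s H+\n",
              format_chon(x$substrate_formula), r(x$nh4_coeff), r(x$o2_coeff),
              r(x$biomass_coeff), format_chon(x$biomass_formula),
              r(x$co2_coeff), r(x$h2o_coeff), r(x$hplus_coeff)))
  cat("max |balance residual|: ",
      format(max(abs(x$residuals)), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Coefficients of a growth stoichiometry as a flat list
#'
#' Convenience accessor for report emission (e.g. JSON): full-precision
#' coefficients plus the balance residuals.
#'
#' @param stoich A `growth_stoichiometry`.
#' @return A named list.
#' @export
stoichiometry_coefficients <- function(stoich) {
  stopifnot(inherits(stoich, "growth_stoichiometry"))
  list(substrate = stoich$substrate_coeff, nh4 = stoich$nh4_coeff,
       o2 = stoich$o2_coeff, biomass = stoich$biomass_coeff,
       co2 = stoich$co2_coeff, h2o = stoich$h2o_coeff,
       hplus = stoich$hplus_coeff,
       residuals = as.list(stoich$residuals))
}
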