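#' Monoisotopic masses of the elements handled by the package
#'
#' Masses of the most abundant isotope, in Da. Restricted to the elements
#' occurring in the lipid classes covered by the reference table.
#' @keywords internal
.element_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.9637064864
)

.mass_proton <- 1.007276466
.mass_electron <- 0.000548579909
.mass_neutron_c13 <- 1.0033548378  # C13 - C12 spacing used for isotopologues

#' Monoisotopic mass of an elemental formula
#'
#' Computes the sum of most-abundant-isotope masses for a Hill-style
#' elemental formula such as `"C45H76O2"`. Only the elements C, H, N, O, P,
#' S, Na and K are supported; anything else is an error. An empty formula
#' has mass 0.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.0106
#' monoisotopic_mass("C45H76O2")   # CE(18:2)
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(0)
    if (grepl("[^A-Za-z0-9]", f)) stop("malformed formula: ", f)
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (sum(nchar(parts)) != nchar(f)) stop("malformed formula: ", f)
    total <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      n <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.element_masses))
        stop("unknown element '", el, "' in formula ", f)
      total <- total + .element_masses[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count atoms of one element in a formula
#' @keywords internal
count_element <- function(formula, element = "C") {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(0L)
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    n <- 0L
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      if (el == element) {
        k <- sub("^[A-Za-z]+", "", p)
        n <- n + if (nzchar(k)) as.integer(k) else 1L
      }
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}

#' Adduct m/z for a neutral monoisotopic mass
#'
#' Singly charged adducts only (the lipid MALDI regime): `[M+H]+`,
#' `[M+Na]+`, `[M+K]+` in positive mode, `[M-H]-` in negative mode. The
#' electron mass is accounted for in the cation masses.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"`, `"[M-H]-"`.
#' @return m/z in Da.
#' @export
adduct_mz <- function(mass, adduct) {
  shift <- adduct_shifts()
  if (any(!adduct %in% names(shift))) {
    stop("unknown adduct: ", paste(setdiff(adduct, names(shift)), collapse = ", "))
  }
  mass + unname(shift[adduct])
}

#' @rdname adduct_mz
#' @export
adduct_shifts <- function() {
  c("[M+H]+"  = .mass_proton,
    "[M+Na]+" = .element_masses[["Na"]] - .mass_electron,
    "[M+K]+"  = .element_masses[["K"]] - .mass_electron,
    "[M-H]-"  = -.mass_proton)
}

#' Adducts considered per ionization polarity
#' @param polarity `"positive"` or `"negative"`.
#' @return Character vector of adduct labels.
#' @export
polarity_adducts <- function(polarity) {
  switch(match.arg(polarity, c("positive", "negative")),
    positive = c("[M+H]+", "[M+Na]+", "[M+K]+"),
    negative = "[M-H]-")
}

#' Signed mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed_mz,theoretical_mz m/z values in Da; `theoretical_mz`
#'   must be positive.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  stopifnot(all(theoretical_mz > 0))
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}
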