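#' Elemental formula for a lipid species from its class and composition
#'
#' Builds a sum-composition elemental formula for the lipid classes covered
#' by the package, from the total number of acyl/backbone carbons and
#' double bonds. Glycerophospholipid templates follow the diacyl (or, with
#' `ether = TRUE`, the 1-O-alkyl ether) composition; sphingolipid templates
#' assume the common d-18 sphingoid backbone is included in the carbon
#' count. These templates reproduce textbook formulas, e.g. PC(34:1) =
#' C42H82NO8P, PI(38:4) = C47H83O13P, CE(18:2) = C45H76O2.
#'
#' @param class Lipid class shorthand (PC, PE, PS, PA, PI, LPC, LPE, LPA,
#'   LPS, LPI, SM, Cer, CerP, CerPE, CerPI, HexCer, Hex2Cer, CE, TAG, DAG,
#'   FFA).
#' @param carbons Total acyl-chain (plus sphingoid backbone) carbons.
#' @param db Total double-bond equivalents in the chains.
#' @param ether Ether-linked (O-) variant for PC, PE, PA, PI.
#' @return Elemental formula string.
#' @export
lipid_formula <- function(class, carbons, db, ether = FALSE) {
  c <- carbons; d <- db
  f <- function(nc, nh, no, extra = "") {
    stopifnot(nc > 0, nh > 0, no >= 0)
    paste0("C", nc, "H", nh, extra, if (no > 0) paste0("O", no) else "")
  }
  if (ether && !class %in% c("PC", "PE", "PA", "PI"))
    stop("ether variant not defined for class ", class)
  switch(class,
    PC  = if (ether) f(c + 8, 2 * c + 18 - 2 * d, 7, "N") %p% "P"
          else       f(c + 8, 2 * c + 16 - 2 * d, 8, "N") %p% "P",
    PE  = if (ether) f(c + 5, 2 * c + 12 - 2 * d, 7, "N") %p% "P"
          else       f(c + 5, 2 * c + 10 - 2 * d, 8, "N") %p% "P",
    PS  = f(c + 6, 2 * c + 10 - 2 * d, 10, "N") %p% "P",
    PA  = if (ether) f(c + 3, 2 * c + 7 - 2 * d, 7) %p% "P"
          else       f(c + 3, 2 * c + 5 - 2 * d, 8) %p% "P",
    PI  = if (ether) f(c + 9, 2 * c + 17 - 2 * d, 12) %p% "P"
          else       f(c + 9, 2 * c + 15 - 2 * d, 13) %p% "P",
    LPC = f(c + 8, 2 * c + 18 - 2 * d, 7, "N") %p% "P",
    LPE = f(c + 5, 2 * c + 12 - 2 * d, 7, "N") %p% "P",
    LPA = f(c + 3, 2 * c + 7 - 2 * d, 7) %p% "P",
    LPS = f(c + 6, 2 * c + 12 - 2 * d, 9, "N") %p% "P",
    LPI = f(c + 9, 2 * c + 17 - 2 * d, 12) %p% "P",
    SM  = f(c + 5, 2 * c + 13 - 2 * d, 6, "N2") %p% "P",
    Cer = f(c, 2 * c + 1 - 2 * d, 3, "N"),
    CerP  = f(c, 2 * c + 2 - 2 * d, 6, "N") %p% "P",
    CerPE = f(c + 2, 2 * c + 7 - 2 * d, 6, "N2") %p% "P",
    CerPI = f(c + 6, 2 * c + 12 - 2 * d, 11, "N") %p% "P",
    HexCer  = f(c + 6, 2 * c + 11 - 2 * d, 8, "N"),
    Hex2Cer = f(c + 12, 2 * c + 21 - 2 * d, 13, "N"),
    CE  = f(c + 27, 2 * c + 44 - 2 * d, 2),
    TAG = f(c + 3, 2 * c + 2 - 2 * d, 6),
    DAG = f(c + 3, 2 * c + 4 - 2 * d, 5),
    FFA = f(c, 2 * c - 2 * d, 2),
    stop("unknown lipid class: ", class)
  )
}

`%p%` <- function(a, b) paste0(a, b)

#' Shorthand name, e.g. PC(34:1) or PC(O-34:1)
#' @keywords internal
lipid_name <- function(class, carbons, db, ether = FALSE) {
  paste0(class, "(", if (ether) "O-" else "", carbons, ":", db, ")")
}

#' Build the bundled synthetic lipid reference table
#'
#' Enumerates ~180 sum-composition species across the 18 lipid classes seen
#' in arterial MALDI-MSI lipidomics (sterols, LPC, PC, SM, CE, DAG, TAG in
#' positive mode; FFA, ST, lyso-phospholipids, PA, PE, PS, PI and ceramide
#' subclasses in negative mode), with elemental formulas from
#' [lipid_formula()] and monoisotopic masses. This is a synthetic stand-in
#' for a full database download, adequate for exact-mass annotation of the
#' phantoms and small studies.
#'
#' @return `data.frame` with columns `name`, `class`, `formula`, `mass`.
#' @export
build_reference_table <- function() {
  rows <- list()
  add <- function(class, carbons, db, ether = FALSE, name = NULL, formula = NULL) {
    if (is.null(formula)) formula <- lipid_formula(class, carbons, db, ether)
    if (is.null(name)) name <- lipid_name(class, carbons, db, ether)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, class = class, formula = formula,
      mass = monoisotopic_mass(formula), stringsAsFactors = FALSE)
  }
  for (cl in c("PC", "PE", "PS", "PA", "PI"))
    for (c in c(32, 34, 36, 38, 40))
      for (d in c(1, 2, 4)) add(cl, c, d)
  for (cd in list(c(34, 1), c(36, 4), c(38, 5), c(40, 5), c(40, 6)))
    add("PC", cd[1], cd[2], ether = TRUE)
  for (cd in list(c(36, 2), c(38, 4), c(40, 6)))
    add("PE", cd[1], cd[2], ether = TRUE)
  add("PA", 40, 6, ether = TRUE)
  add("PI", 38, 4, ether = TRUE)
  for (cd in list(c(16, 0), c(18, 0), c(18, 1), c(20, 4))) add("LPC", cd[1], cd[2])
  for (cd in list(c(16, 0), c(18, 0), c(18, 1))) add("LPE", cd[1], cd[2])
  for (cd in list(c(16, 0), c(18, 0), c(18, 1))) add("LPA", cd[1], cd[2])
  for (cd in list(c(18, 0), c(18, 1))) add("LPS", cd[1], cd[2])
  for (cd in list(c(18, 0), c(18, 1), c(20, 4))) add("LPI", cd[1], cd[2])
  for (c in c(34, 36, 38, 40, 42)) for (d in c(1, 2)) add("SM", c, d)
  for (cd in list(c(34, 1), c(36, 1), c(38, 1), c(40, 1), c(42, 1), c(42, 2)))
    add("Cer", cd[1], cd[2])
  for (cd in list(c(34, 1), c(36, 1), c(38, 1))) add("CerP", cd[1], cd[2])
  for (cd in list(c(36, 1), c(38, 1), c(40, 1))) add("CerPE", cd[1], cd[2])
  for (cd in list(c(36, 1), c(38, 1))) add("CerPI", cd[1], cd[2])
  for (cd in list(c(34, 1), c(36, 1), c(38, 1), c(40, 1))) add("HexCer", cd[1], cd[2])
  for (cd in list(c(34, 1), c(38, 1))) add("Hex2Cer", cd[1], cd[2])
  for (cd in list(c(14, 0), c(16, 0), c(16, 1), c(18, 0), c(18, 1), c(18, 2),
                  c(18, 3), c(20, 4), c(22, 6))) add("CE", cd[1], cd[2])
  for (c in c(48, 50, 52, 54, 56)) for (d in c(1, 2, 3)) add("TAG", c, d)
  for (cd in list(c(32, 0), c(34, 1), c(36, 2), c(36, 4))) add("DAG", cd[1], cd[2])
  for (cd in list(c(16, 0), c(16, 1), c(18, 0), c(18, 1), c(18, 2), c(20, 4),
                  c(22, 6))) add("FFA", cd[1], cd[2])
  # sterols are special-cased (ring systems, not chain compositions)
  add("ST", NA, NA, name = "cholesterol", formula = "C27H46O")
  add("ST", NA, NA, name = "7-ketocholesterol", formula = "C27H44O2")
  add("ST", NA, NA, name = "ST(27:2;O)", formula = "C27H44O")
  add("ST", NA, NA, name = "ST(28:1;O)", formula = "C28H48O")
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$name))
  rownames(out) <- NULL
  out
}

#' Read a lipid reference table from CSV
#'
#' Columns `name`, `class`, and `formula` and/or `mass` are required. When
#' both are present each formula is checked against the stated mass
#' (within 1e-4 Da); when only a formula is given the mass is computed.
#'
#' @param path CSV path; defaults to the bundled synthetic table.
#' @return `data.frame` with columns `name`, `class`, `formula`, `mass`.
#' @export
read_reference_table <- function(path = system.file("extdata",
    "lipid_reference_synthetic.csv", package = "lipidmsi")) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "class") %in% names(ref)))
    stop("reference table needs 'name' and 'class' columns")
  has_formula <- "formula" %in% names(ref) && any(nzchar(ref$formula))
  if (!has_formula && !"mass" %in% names(ref))
    stop("reference table needs a 'formula' or 'mass' column")
  if (!"mass" %in% names(ref)) ref$mass <- monoisotopic_mass(ref$formula)
  if (has_formula) {
    calc <- monoisotopic_mass(ref$formula)
    bad <- which(abs(calc - ref$mass) > 1e-4)
    if (length(bad))
      stop("formula/mass mismatch for: ", paste(ref$name[bad], collapse = ", "))
  }
  if (any(ref$mass <= 0)) stop("non-positive mass in reference table")
  ref
}
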