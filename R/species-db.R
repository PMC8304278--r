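# Anion mass database and exact-mass arithmetic.
#
# All masses are monoisotopic, in Da, from the IUPAC/CODATA isotopic mass
# tables. The analytes are the free acids of the condensed phosphates; they
# are observed as singly deprotonated anions [M-H]- in negative mode.

#' Monoisotopic masses of the elements used by the phosphate database
#'
#' Named vector of monoisotopic masses (Da) for the element and isotope
#' symbols the package understands. Isotope labels are first-class symbols
#' (`"15N"`), so the nitrate internal standard is an ordinary composition.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' element_masses()[["P"]]
element_masses <- function() {
  c(
    H     = 1.00782503207,
    C     = 12.0,
    N     = 14.0030740048,
    `15N` = 15.0001088982,
    O     = 15.9949146196,
    P     = 30.97376163,
    Na    = 22.9897692809,
    S     = 31.97207100,
    K     = 38.96370668
  )
}

# mass of the proton (Da); removed when forming [M-H]-
PROTON_MASS <- 1.00727646688

# formula mass of P2O5, the unit regulation uses for phosphate totals
P2O5_MASS <- 2 * 30.97376163 + 5 * 15.9949146196

#' Parse a molecular formula into an elemental composition
#'
#' Understands plain element symbols with optional counts (`"H3PO4"`) and
#' bracketed isotope labels (`"H[15N]O3"`). Counts default to 1.
#'
#' @param formula Character scalar, e.g. `"H4P2O7"`.
#' @return Named integer vector (element/isotope symbol -> count).
#' @export
#' @examples
#' parse_formula("H3PO4")
#' parse_formula("H[15N]O3")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) {
    stop("empty formula: an elemental composition needs at least one element",
         call. = FALSE)
  }
  known <- names(element_masses())
  pat <- "(\\[[0-9]+[A-Za-z]+\\]|[A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  sym <- gsub("[0-9]*$", "", toks)
  sym <- gsub("\\[|\\]", "", sym)
  cnt <- sub("^\\[?[0-9]*[A-Za-z]+\\]?", "", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  bad <- setdiff(unique(sym), known)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(cnt < 1L)) stop("element counts must be >= 1", call. = FALSE)
  out <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named integer vector as returned by [parse_formula()],
#'   or a formula string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H3PO4")
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0L) {
    stop("empty composition: invalid formula", call. = FALSE)
  }
  masses <- element_masses()
  bad <- setdiff(names(composition), names(masses))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(composition < 1)) stop("element counts must be >= 1", call. = FALSE)
  sum(masses[names(composition)] * composition)
}

#' m/z of the deprotonated anion \[M-H\]-
#'
#' The negative-mode precursor of each (poly)phosphoric acid: the neutral
#' monoisotopic mass minus one proton.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Th.
#' @export
#' @examples
#' mz_deprotonated("H3PO4")  # orthophosphate precursor
mz_deprotonated <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (is.na(composition["H"]) || composition[["H"]] < 1L) {
    stop("composition has no hydrogen to remove; [M-H]- undefined",
         call. = FALSE)
  }
  monoisotopic_mass(composition) - PROTON_MASS
}

#' Convert between species mass and P2O5 equivalents
#'
#' Regulation expresses (poly)phosphate totals as the stoichiometrically
#' corresponding mass of phosphorus pentoxide: each phosphorus atom of the
#' free acid counts as half a P2O5 unit. `p2o5_equivalent()` converts a
#' species amount (free-acid basis) to µg P2O5; `from_p2o5()` is the inverse,
#' used to express P2O5-denominated standards on the species scale.
#'
#' @param amount Amount of the species in µg (free acid), or µg P2O5 for
#'   `from_p2o5()`.
#' @param species A one-row slice of [phosphate_species()], or a species name.
#' @return Amount in µg P2O5 (resp. µg of species).
#' @export
#' @examples
#' p2o5_equivalent(100, "orthophosphate")
p2o5_equivalent <- function(amount, species) {
  sp <- resolve_species(species)
  if (sp$n_phosphorus < 1L) {
    stop("species contains no phosphorus; P2O5 equivalent undefined",
         call. = FALSE)
  }
  amount * p2o5_factor(sp)
}

#' @rdname p2o5_equivalent
#' @export
from_p2o5 <- function(amount, species) {
  sp <- resolve_species(species)
  if (sp$n_phosphorus < 1L) {
    stop("species contains no phosphorus; P2O5 equivalent undefined",
         call. = FALSE)
  }
  amount / p2o5_factor(sp)
}

#' @rdname p2o5_equivalent
#' @export
p2o5_factor <- function(species) {
  sp <- resolve_species(species)
  sp$n_phosphorus * (P2O5_MASS / 2) / monoisotopic_mass(sp$composition[[1]])
}

resolve_species <- function(species) {
  if (is.character(species)) {
    db <- phosphate_species()
    hit <- db[db$name == species, ]
    if (nrow(hit) != 1L) {
      stop("unknown species name: ", species, call. = FALSE)
    }
    return(hit)
  }
  stopifnot(is.data.frame(species), nrow(species) == 1L)
  species
}

#' The (poly)phosphate anion database
#'
#' One row per target anion: elemental composition of the neutral free acid,
#' expected retention time (min) on the anion-exchange gradient, the
#' deprotonated-precursor m/z as printed in the method database and as
#' computed from the composition, and the confirmation fragment m/z values
#' observed in the DIA segment. Computed masses are authoritative for
#' matching; printed values are retained for provenance. Two printed
#' fragments conflict with assignable ions (see `fragment_mzs` vs
#' `fragments_printed`): the pyrophosphate 78.9561 entry is the PO3- ion
#' (computed 78.9591), and the triphosphate 176.9685 entry corresponds to no
#' assignable composition (HPO3 loss gives 176.9359) and is matched at the
#' computed value, flagged unverified.
#'
#' The long-chain set — tetra-, tetrameta-, penta-, pentameta-, hexa- and
#' hexametaphosphate — has no commercial reference standards; those species
#' are identification-only (`quantifiable = FALSE`) and jointly constitute
#' the E452 confirmation fingerprint.
#'
#' @return A tibble with columns `name`, `formula`, `composition`
#'   (list-column), `expected_rt`, `precursor_printed`, `precursor_mz`,
#'   `fragments_printed`, `fragment_mzs` (list-columns), `n_phosphorus`,
#'   `chain_class`, `quantifiable`.
#' @export
#' @examples
#' phosphate_species()
phosphate_species <- function() {
  db <- tibble::tribble(
    ~name,                 ~formula,    ~expected_rt, ~precursor_printed, ~fragments_printed,             ~chain_class,        ~quantifiable,
    "orthophosphate",      "H3PO4",      5.9,  96.9696, list(78.9590),            "ortho",             TRUE,
    "internal_standard",   "H[15N]O3",   7.0,  62.9854, list(numeric(0)),         "internal_standard", FALSE,
    "pyrophosphate",       "H4P2O7",     9.0, 176.9359, list(c(78.9561, 96.9697)),"short_linear",      TRUE,
    "triphosphate",        "H5P3O10",   11.8, 256.9023, list(c(96.9697, 176.9685)),"short_linear",     TRUE,
    "trimetaphosphate",    "H3P3O9",    13.5, 238.8917, list(c(118.9422, 158.9253)),"short_cyclic",    TRUE,
    "tetraphosphate",      "H6P4O13",   15.6, 336.8686, list(c(78.9591, 256.9025)),"long_linear",      FALSE,
    "tetrametaphosphate",  "H4P4O12",   16.8, 318.8580, list(c(158.9254, 256.9025)),"long_cyclic",     FALSE,
    "pentaphosphate",      "H7P5O16",   17.9, 416.8349, list(c(256.9025, 336.8689)),"long_linear",     FALSE,
    "pentametaphosphate",  "H5P5O15",   18.9, 398.8244, list(c(198.9086, 318.8582)),"long_cyclic",     FALSE,
    "hexametaphosphate",   "H6P6O18",   18.7, 478.7907, list(c(238.8919, 318.8582)),"long_cyclic",     FALSE,
    "hexaphosphate",       "H8P6O19",   21.7, 496.8013, list(c(247.8970, 336.8689)),"long_linear",     FALSE
  )
  db$fragments_printed <- purrr::map(db$fragments_printed,
                                     function(x) as.numeric(unlist(x)))
  db$composition <- purrr::map(db$formula, parse_formula)
  db$precursor_mz <- purrr::map_dbl(db$composition, mz_deprotonated)
  db$n_phosphorus <- purrr::map_dbl(
    db$composition, function(x) sum(x[names(x) == "P"])
  )
  db$n_phosphorus <- as.integer(db$n_phosphorus)
  # matching fragment list: printed values, with assignable ions replaced by
  # their computed masses (PO3-, and fragments that are another species'
  # precursor or a known anhydride loss)
  po3 <- monoisotopic_mass(c(P = 1L, O = 3L)) + 5.48579909e-4  # PO3- = P+3O+e
  computed_frag <- function(fr) {
    vapply(fr, function(v) {
      # PO3- printed with either 78.9590/78.9591 rounding or the 78.9561 typo
      if (abs(v - 78.959) < 0.004) return(po3)
      # precursors of smaller chains seen as in-source/DIA fragments
      pre <- db$precursor_mz
      i <- which(abs(v - pre) < 0.0335)
      if (length(i) == 1L) return(pre[i])
      v
    }, numeric(1))
  }
  db$fragment_mzs <- purrr::map(db$fragments_printed, computed_frag)
  db <- db[order(db$expected_rt), ]
  db[, c("name", "formula", "composition", "expected_rt",
         "precursor_printed", "precursor_mz",
         "fragments_printed", "fragment_mzs",
         "n_phosphorus", "chain_class", "quantifiable")]
}

#' Names of the long-chain fingerprint species
#' @return Character vector of six species names, in elution order.
#' @export
longchain_species <- function() {
  db <- phosphate_species()
  db$name[db$chain_class %in% c("long_linear", "long_cyclic")]
}

#' Read/write the species database as a delimited table
#'
#' Serialises the database to a CSV mirroring the method-database layout
#' (name, formula, RT, precursor, fragments semicolon-separated). Fragment
#' and composition list-columns are reconstructed on read.
#'
#' @param db A tibble as from [phosphate_species()].
#' @param path File path.
#' @return `read_species_db()` returns the database tibble.
#' @export
write_species_db <- function(db, path) {
  flat <- data.frame(
    name = db$name, formula = db$formula, expected_rt = db$expected_rt,
    precursor_printed = db$precursor_printed,
    fragments_printed = vapply(
      db$fragments_printed, function(x) paste(format(x, nsmall = 4, trim = TRUE), collapse = ";"),
      character(1)
    ),
    chain_class = db$chain_class, quantifiable = db$quantifiable,
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_db
#' @export
read_species_db <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  db <- tibble::as_tibble(flat)
  db$fragments_printed <- purrr::map(
    strsplit(ifelse(is.na(db$fragments_printed), "", db$fragments_printed), ";"),
    function(x) as.numeric(x[nzchar(x)])
  )
  db$composition <- purrr::map(db$formula, parse_formula)
  db$precursor_mz <- purrr::map_dbl(db$composition, mz_deprotonated)
  db$n_phosphorus <- vapply(
    db$composition, function(x) as.integer(sum(x[names(x) == "P"])), integer(1)
  )
  db
}
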