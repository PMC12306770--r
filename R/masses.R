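# Monoisotopic masses of the elements occurring in peptides, sugars and the
# small metabolites handled here (most abundant isotope of each element).
.element_masses <- c(
  C = 12.0000000,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Mass of a proton, in Da
#'
#' The m/z of an \eqn{[M+H]^+} adduct is the neutral monoisotopic mass plus
#' this value; \eqn{[M-H]^-} subtracts it.
#' @export
proton_mass <- 1.007276

#' Monoisotopic mass of water, in Da
#'
#' Lost on peptide-bond and glycosidic-bond condensation.
#' @export
water_mass <- 18.010565

#' Compute the monoisotopic mass of a molecular formula
#'
#' Parses Hill-notation formulas such as `"C6H12O6"` (elements C, H, N, O, S,
#' P; counts default to 1) and sums the monoisotopic masses of the most
#' abundant isotopes.
#'
#' @param formula Character vector of molecular formulas.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' formula_mass("C6H12O6") # glucose, 180.0634
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) {
      return(NA_real_)
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!nzchar(f) || sum(nchar(toks)) != nchar(f)) {
      abort(paste0("cannot parse formula: ", f))
    }
    total <- 0
    for (tok in toks) {
      el <- gsub("[0-9]", "", tok)
      cnt <- gsub("[^0-9]", "", tok)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.element_masses)) {
        abort(paste0("unsupported element '", el, "' in formula ", f))
      }
      total <- total + .element_masses[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

# Residue formulas of the 20 proteinogenic amino acids (the amino acid minus
# one water). Leucine and isoleucine are isobaric but kept as distinct
# residues.
.residue_formulas <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Monoisotopic residue masses of the proteinogenic amino acids
#'
#' @return A tibble with one row per canonical residue: `residue` (one-letter
#'   code), `formula` (residue formula, i.e. the amino acid minus water) and
#'   `residue_mass` (Da). A free amino acid weighs `residue_mass + water_mass`.
#' @export
amino_acid_residues <- function() {
  tibble(
    residue = names(.residue_formulas),
    formula = unname(.residue_formulas),
    residue_mass = formula_mass(unname(.residue_formulas))
  )
}

# All multisets of size k from n items, as a matrix of non-decreasing index
# tuples (one row per multiset).
.multisets <- function(n, k) {
  if (k == 1L) {
    return(matrix(seq_len(n), ncol = 1L))
  }
  sub <- .multisets(n, k - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- sub[sub[, 1L] >= i, , drop = FALSE]
    out[[i]] <- cbind(i, keep)
  }
  do.call(rbind, out)
}

#' Enumerate short peptides by amino-acid composition
#'
#' Enumerates every amino-acid multiset of length 1 to `max_len` over the 20
#' canonical residues. Peptide mass is order-independent, so one catalog entry
#' per composition suffices for exact-mass annotation; the number of distinct
#' sequences each composition represents is reported alongside.
#'
#' @param max_len Maximum peptide length (default 4, i.e. peptides of four or
#'   fewer amino acids).
#' @return A tibble with columns `label` (residues in alphabetical order),
#'   `mass` (neutral monoisotopic mass: sum of residue masses plus one water),
#'   `length`, `n_sequences` (multinomial count of orderings) and
#'   `source = "peptide"`. At `max_len = 4` there are 10,625 compositions
#'   covering 168,420 sequences.
#' @export
enumerate_peptides <- function(max_len = 4) {
  if (!is.numeric(max_len) || length(max_len) != 1L || max_len < 1) {
    abort("max_len must be a single integer >= 1")
  }
  max_len <- as.integer(max_len)
  res <- amino_acid_residues()
  ord <- order(res$residue)
  letters_sorted <- res$residue[ord]
  masses_sorted <- res$residue_mass[ord]
  pieces <- vector("list", max_len)
  for (k in seq_len(max_len)) {
    idx <- .multisets(length(letters_sorted), k)
    mass <- rowSums(matrix(masses_sorted[idx], nrow = nrow(idx))) + water_mass
    label <- apply(idx, 1L, function(i) paste(letters_sorted[i], collapse = ""))
    n_seq <- apply(idx, 1L, function(i) {
      tab <- tabulate(i, nbins = length(letters_sorted))
      factorial(k) / prod(factorial(tab))
    })
    pieces[[k]] <- tibble(
      label = label, mass = mass, length = k,
      n_sequences = n_seq, source = "peptide"
    )
  }
  bind_rows(pieces)
}

#' Amino-sugar monomer and dimer masses
#'
#' Neutral monoisotopic masses of the amino-sugar degradation products
#' expected from EPS polysaccharide hydrolysis: hexosamine (e.g. glucosamine,
#' C6H13NO5), N-acetylhexosamine (e.g. GlcNAc, C8H15NO6), and their glycosidic
#' dimers (two monomers minus one water).
#'
#' @return A tibble with columns `label`, `formula` (monomers only), `mass`
#'   and `source = "sugar"`.
#' @export
sugar_masses <- function() {
  hexn <- formula_mass("C6H13NO5")
  hexnac <- formula_mass("C8H15NO6")
  tibble(
    label = c(
      "hexosamine", "N-acetylhexosamine",
      "hexosamine dimer", "N-acetylhexosamine dimer",
      "hexosamine-N-acetylhexosamine dimer"
    ),
    formula = c("C6H13NO5", "C8H15NO6", NA, NA, NA),
    mass = c(
      hexn, hexnac,
      2 * hexn - water_mass, 2 * hexnac - water_mass,
      hexn + hexnac - water_mass
    ),
    source = "sugar"
  )
}

#' Assemble an exact-mass annotation catalog
#'
#' Combines the combinatorial peptide catalog, the amino-sugar catalog and an
#' optional user-supplied compound table into a single catalog for
#' [annotate_ions()].
#'
#' @param peptides Include peptides up to `max_len` residues? Default `TRUE`.
#' @param sugars Include amino-sugar monomers and dimers? Default `TRUE`.
#' @param user Optional data frame of compounds with a `label` column and
#'   either a `mass` (neutral monoisotopic, Da) or a `formula` column
#'   (BioCyc-style compound exports reduce to this layout).
#' @param max_len Maximum peptide length passed to [enumerate_peptides()].
#' @return A tibble with columns `label`, `mass`, `source`, sorted by mass.
#' @export
mass_catalog <- function(peptides = TRUE, sugars = TRUE, user = NULL,
                         max_len = 4) {
  parts <- list()
  if (peptides) {
    parts$pep <- enumerate_peptides(max_len)[, c("label", "mass", "source")]
  }
  if (sugars) {
    parts$sug <- sugar_masses()[, c("label", "mass", "source")]
  }
  if (!is.null(user)) {
    user <- as_tibble(user)
    if (!"label" %in% names(user)) {
      abort("user compound table needs a 'label' column")
    }
    if (!"mass" %in% names(user)) {
      if (!"formula" %in% names(user)) {
        abort("user compound table needs a 'mass' or 'formula' column")
      }
      user$mass <- formula_mass(user$formula)
    }
    user$source <- "user"
    parts$user <- user[, c("label", "mass", "source")]
  }
  if (length(parts) == 0L) {
    abort("empty catalog: enable at least one source")
  }
  cat <- bind_rows(parts)
  if (any(!is.finite(cat$mass)) || any(cat$mass <= 0)) {
    abort("catalog masses must be positive and finite")
  }
  dup <- cat |>
    dplyr::count(.data$source, .data$label) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort("catalog labels must be unique within each source")
  }
  arrange(cat, .data$mass)
}
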