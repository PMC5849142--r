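# Elemental composition, molecular mass and ESI-MS charge-state ladders.
#
# Masses use the neutral free-acid convention: every sulfo group as -SO3H,
# every carboxyl as -COOH. This is the convention under which ESI-MS
# deconvoluted masses of these compounds are reported.

# IUPAC 2013 conventional atomic weights; principal-isotope masses for the
# monoisotopic path. Stored to 5 decimals.
.ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                     S = 32.06, F = 18.99840)
.MONO_MASSES <- c(C = 12.0, H = 1.00783, N = 14.00307, O = 15.99491,
                  S = 31.97207, F = 18.99840)
# atomic mass of hydrogen used for the deprotonation arithmetic of
# negative-mode ESI ladders
.H_MASS <- 1.00794

.elem_zero <- function() c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L, F = 0L)

.elem <- function(C = 0, H = 0, N = 0, O = 0, S = 0, F = 0) {
  c(C = as.integer(C), H = as.integer(H), N = as.integer(N),
    O = as.integer(O), S = as.integer(S), F = as.integer(F))
}

# free (unlinked) monosaccharide compositions
.BASE_URONIC <- .elem(C = 6, H = 10, O = 7)   # glucuronic / iduronic acid
.BASE_GLCN <- .elem(C = 6, H = 13, N = 1, O = 5)  # glucosamine, free amine
.SO3 <- .elem(S = 1, O = 3)                   # sulfation: -XH -> -X-SO3H
.ACETYL <- .elem(C = 2, H = 2, O = 1)         # -NH2 -> -NH-COCH3
.TFA <- .elem(C = 2, H = -1, O = 1, F = 3)    # -NH2 -> -NH-COCF3
.H2O <- .elem(H = 2, O = 1)
# aglycone phenols, condensed with the anomeric OH with loss of water
.AGLYCONE_PHENOL <- list(
  "pNA-N3" = .elem(C = 12, H = 16, N = 4, O = 2),  # N-(6-azidohexanamidyl) p-aminophenol
  "pNP" = .elem(C = 6, H = 5, N = 1, O = 3),       # p-nitrophenol
  "free" = .elem_zero()
)

.residue_composition <- function(residue) {
  if (residue$ring == .RING_GLCN) {
    comp <- .BASE_GLCN +
      switch(residue$n_sub, acetyl = .ACETYL, tfa = .TFA, sulfo = .SO3,
             free = .elem_zero())
  } else {
    comp <- .BASE_URONIC
  }
  comp + length(residue$o_sulfo) * .SO3
}

#' Elemental composition of an oligosaccharide
#'
#' Free-acid convention: sulfo groups counted as -SO3H and carboxyls as
#' -COOH. The chain composition is the sum of the free monosaccharide
#' compositions minus one water per glycosidic bond; a reducing-end
#' aglycone is counted as condensation of the corresponding phenol with
#' loss of one further water.
#'
#' @param oligo an `hs_oligo`.
#' @return named integer vector of class `hs_composition` with counts for
#'   C, H, N, O, S, F.
#' @examples
#' elemental_composition(parse_sequence("GlcA-pNA-N3"))
#' @export
elemental_composition <- function(oligo) {
  stopifnot(inherits(oligo, "hs_oligo"))
  res <- residues(oligo)
  comp <- Reduce(`+`, lapply(res, .residue_composition))
  comp <- comp - (length(res) - 1L) * .H2O
  if (oligo$aglycone != "free")
    comp <- comp + .AGLYCONE_PHENOL[[oligo$aglycone]] - .H2O
  structure(comp, class = "hs_composition")
}

#' @export
print.hs_composition <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Render a composition as a Hill-style formula string
#'
#' @param comp an `hs_composition` (or named count vector).
#' @return character scalar, e.g. `"C48H73N7O56S8"`.
#' @export
format_formula <- function(comp) {
  comp <- comp[comp != 0]
  # Hill order: C, H, then the remaining elements alphabetically
  ord <- c(intersect(c("C", "H"), names(comp)),
           sort(setdiff(names(comp), c("C", "H"))))
  comp <- comp[ord]
  paste0(names(comp), ifelse(comp == 1L, "", comp), collapse = "")
}

#' Average and monoisotopic molecular mass
#'
#' Both masses are computed from the same elemental composition: the
#' average from standard atomic weights, the monoisotopic from
#' principal-isotope masses.
#'
#' @param oligo an `hs_oligo`.
#' @return list of class `hs_mass`: `average`, `monoisotopic` (Da),
#'   `formula` and `composition`.
#' @examples
#' oligo_mass(get_fixture("14")$oligo)   # average 1900.6 Da
#' @export
oligo_mass <- function(oligo) {
  comp <- elemental_composition(oligo)
  structure(list(
    average = sum(unclass(comp) * .ATOMIC_WEIGHTS[names(comp)]),
    monoisotopic = sum(unclass(comp) * .MONO_MASSES[names(comp)]),
    formula = format_formula(comp),
    composition = comp
  ), class = "hs_mass")
}

#' @export
print.hs_mass <- function(x, ...) {
  cat(sprintf("%s  average %.1f Da, monoisotopic %.1f Da\n",
              x$formula, x$average, x$monoisotopic))
  invisible(x)
}

#' Average molecular mass (Da)
#'
#' Convenience wrapper around [oligo_mass()].
#'
#' @param oligo an `hs_oligo`.
#' @return numeric scalar, Da.
#' @export
average_mass <- function(oligo) oligo_mass(oligo)$average

#' Monoisotopic molecular mass (Da)
#'
#' @param oligo an `hs_oligo`.
#' @return numeric scalar, Da.
#' @export
monoisotopic_mass <- function(oligo) oligo_mass(oligo)$monoisotopic

#' Negative-mode ESI charge-state ladder
#'
#' m/z values of the deprotonated molecular ions \eqn{[M - zH]^{z-}}:
#' \eqn{m/z = (M - z \cdot m_H)/z}. Highly sulfated oligosaccharides
#' ionize readily in negative mode at several charge states (compound-14
#' class hexasaccharides show z = 4, 5, 6).
#'
#' @param mass neutral molecular mass M in Da (positive scalar).
#' @param charges integer vector of charge states z, all >= 1.
#' @return data.frame of class `hs_esi_ladder` with columns `z`, `mz`,
#'   sorted by `z`; `mz` is strictly decreasing in `z`.
#' @examples
#' esi_ladder(1900.6, 4:6)
#' @export
esi_ladder <- function(mass, charges) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0)
  charges <- as.integer(charges)
  if (length(charges) == 0L || any(charges < 1L))
    stop("charge states must be positive integers", call. = FALSE)
  charges <- sort(unique(charges))
  out <- data.frame(z = charges, mz = (mass - charges * .H_MASS) / charges)
  class(out) <- c("hs_esi_ladder", "data.frame")
  out
}

#' @export
print.hs_esi_ladder <- function(x, ...) {
  cat("Negative-mode ESI ladder [M - zH]^z-\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  z = %d   m/z = %.2f\n", x$z[i], x$mz[i]))
  invisible(x)
}
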