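# Residue-level vocabulary for the HS/heparin alphabet.
#
# A residue is one pyranose ring of the alternating (1->4)-linked chain:
# either a uronic acid (beta-D-glucuronic acid "GlcA" or its C5 epimer
# alpha-L-iduronic acid "IdoA", optionally 2-O-sulfated) or an
# alpha-D-glucosamine ("GlcN") whose amine is free, N-acetylated,
# N-trifluoroacetylated (a transient protecting group used during
# chemoenzymatic synthesis) or N-sulfated, optionally 3-O- and/or
# 6-O-sulfated.

.RING_GLCA <- "gluco-uronic"
.RING_IDOA <- "ido-uronic"
.RING_GLCN <- "glucosamine"

#' Construct a single residue
#'
#' Low-level constructor for one ring of an HS/heparin chain. Most users
#' should build whole chains with [parse_sequence()] instead.
#'
#' @param ring one of `"gluco-uronic"` (GlcA), `"ido-uronic"` (IdoA),
#'   `"glucosamine"` (GlcN).
#' @param n_sub amine substituent, glucosamine only: `"acetyl"`, `"tfa"`
#'   (N-trifluoroacetyl), `"sulfo"` or `"free"`. Uronic residues take
#'   `"none"`.
#' @param o_sulfo integer vector of O-sulfated ring positions. Uronic
#'   residues admit position 2 only; glucosamine residues admit 3 and 6.
#'   A 3-O-sulfated glucosamine must be N-sulfated (GlcNAc3S does not
#'   occur in this chemistry).
#' @return a list of class `hs_residue` with fields `ring`, `n_sub`,
#'   `o_sulfo` and the derived `anomeric_config` (`"beta"` for
#'   gluco-uronic, `"alpha"` otherwise).
#' @examples
#' hs_residue("glucosamine", "sulfo", c(3, 6))
#' @export
hs_residue <- function(ring, n_sub = if (ring == "glucosamine") "free" else "none",
                       o_sulfo = integer()) {
  rings <- c(.RING_GLCA, .RING_IDOA, .RING_GLCN)
  if (!is.character(ring) || length(ring) != 1L || !ring %in% rings)
    stop("unknown ring type: ", ring, call. = FALSE)
  o_sulfo <- sort(unique(as.integer(o_sulfo)))
  if (ring == .RING_GLCN) {
    if (!n_sub %in% c("acetyl", "tfa", "sulfo", "free"))
      stop("invalid N-substituent for glucosamine: ", n_sub, call. = FALSE)
    if (!all(o_sulfo %in% c(3L, 6L)))
      stop("glucosamine O-sulfo positions must be within {3, 6}", call. = FALSE)
    if (3L %in% o_sulfo && n_sub != "sulfo")
      stop("a 3-O-sulfated glucosamine must be N-sulfated", call. = FALSE)
  } else {
    if (!identical(n_sub, "none"))
      stop("uronic residues carry no N-substituent", call. = FALSE)
    if (!all(o_sulfo %in% 2L))
      stop("uronic O-sulfo positions must be within {2}", call. = FALSE)
  }
  structure(
    list(ring = ring, n_sub = n_sub, o_sulfo = o_sulfo,
         anomeric_config = if (ring == .RING_GLCA) "beta" else "alpha"),
    class = "hs_residue"
  )
}

#' @export
print.hs_residue <- function(x, ...) {
  cat(residue_token(x), " (", x$ring, ", ", x$anomeric_config, ")\n", sep = "")
  invisible(x)
}

# token <-> residue ---------------------------------------------------------

#' Short residue name for a residue object
#'
#' Renders the field-standard short name, e.g. `"GlcNS3S6S"` or `"IdoA2S"`.
#'
#' @param residue an `hs_residue`.
#' @return character scalar.
#' @export
residue_token <- function(residue) {
  stopifnot(inherits(residue, "hs_residue"))
  if (residue$ring == .RING_GLCN) {
    nsfx <- switch(residue$n_sub, acetyl = "Ac", tfa = "TFA", sulfo = "S", free = "")
    paste0("GlcN", nsfx,
           if (3L %in% residue$o_sulfo) "3S" else "",
           if (6L %in% residue$o_sulfo) "6S" else "")
  } else {
    paste0(if (residue$ring == .RING_GLCA) "GlcA" else "IdoA",
           if (2L %in% residue$o_sulfo) "2S" else "")
  }
}

#' Parse a short residue name
#'
#' Inverse of [residue_token()]: `"GlcNS6S"`, `"IdoA2S"`, `"GlcNTFA"`, ...
#'
#' @param token character scalar.
#' @return an `hs_residue`.
#' @export
parse_residue <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  m <- regmatches(token, regexec("^(GlcA|IdoA)(2S)?$", token))[[1]]
  if (length(m)) {
    ring <- if (m[2] == "GlcA") .RING_GLCA else .RING_IDOA
    return(hs_residue(ring, "none", if (nzchar(m[3])) 2L else integer()))
  }
  m <- regmatches(token, regexec("^GlcN(Ac|TFA|S)?(3S)?(6S)?$", token))[[1]]
  if (length(m)) {
    n_sub <- switch(m[2], Ac = "acetyl", TFA = "tfa", S = "sulfo", "free")
    pos <- c(if (nzchar(m[3])) 3L, if (nzchar(m[4])) 6L)
    return(hs_residue(.RING_GLCN, n_sub, pos))
  }
  stop("unknown residue token: '", token, "'", call. = FALSE)
}

# internal predicates on tokens (fast path used by the planner) -------------

.tok_is_uronic <- function(tok) grepl("^(GlcA|IdoA)", tok)
.tok_is_glcn <- function(tok) grepl("^GlcN", tok)
.tok_is_ns_class <- function(tok) grepl("^GlcNS", tok)  # GlcNS, GlcNS6S, GlcNS3S6S
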