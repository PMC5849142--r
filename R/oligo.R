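# The oligosaccharide container and its text grammar.
#
# Chains are stored non-reducing -> reducing: index 1 (label A) is the
# non-reducing end, the last residue carries the aglycone. All glycosidic
# bonds are (1->4); anomeric configuration is a property of the ring type
# (beta for GlcA, alpha for IdoA and GlcN) and is not stored per bond.

.AGLYCONES <- c("pNA-N3", "pNP", "free")

#' Construct an oligosaccharide from residue tokens
#'
#' @param tokens character vector of residue short names, ordered from the
#'   non-reducing end (residue A) to the reducing end.
#' @param aglycone reducing-end tag: `"pNA-N3"` (N-(6-azidohexanamidyl)
#'   p-aminophenyl, the UV-detectable azide tag), `"pNP"` (p-nitrophenyl)
#'   or `"free"`.
#' @return an object of class `hs_oligo`.
#' @details Residue rings must strictly alternate between uronic acid and
#'   glucosamine along the chain; each token must be valid for its ring
#'   type (see [hs_residue()]).
#' @examples
#' hs_oligo_from_tokens(c("GlcA", "GlcNS", "GlcA"), "pNA-N3")
#' @export
hs_oligo_from_tokens <- function(tokens, aglycone = "free") {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  if (!aglycone %in% .AGLYCONES)
    stop("unknown aglycone: ", aglycone, call. = FALSE)
  # validates every token (sulfo-position legality, GlcNAc3S exclusion, ...)
  lapply(tokens, parse_residue)
  uro <- .tok_is_uronic(tokens)
  if (length(tokens) > 1L && any(uro[-1L] == uro[-length(uro)])) {
    i <- which(uro[-1L] == uro[-length(uro)])[1L]
    stop("alternation violation: adjacent residues ", tokens[i], " and ",
         tokens[i + 1L], " have the same ring class", call. = FALSE)
  }
  structure(list(tokens = tokens, aglycone = aglycone), class = "hs_oligo")
}

#' Residue labels (A, B, C, ...)
#'
#' Residues are labelled alphabetically from the non-reducing end, the
#' convention used for NMR assignment of these compounds.
#'
#' @param oligo an `hs_oligo`.
#' @return character vector, one label per residue.
#' @export
residue_labels <- function(oligo) {
  stopifnot(inherits(oligo, "hs_oligo"))
  n <- length(oligo$tokens)
  if (n <= 26L) LETTERS[seq_len(n)] else
    vapply(seq_len(n), function(i) {
      paste0(LETTERS[((i - 1L) %/% 26L)], LETTERS[((i - 1L) %% 26L) + 1L])
    }, "")
}

#' @export
length.hs_oligo <- function(x) length(x$tokens)

#' Parse an oligosaccharide sequence string
#'
#' The grammar follows the field's naming convention: residue short names
#' joined by `"(1-4)"` (ASCII; `"(1->4)"` is also accepted), with an
#' optional aglycone suffix `-pNA-N3` or `-pNP` on the reducing-end
#' residue. Whitespace around tokens is ignored.
#'
#' @param text sequence string, e.g.
#'   `"GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3"`.
#' @return an `hs_oligo`; round-trips through [format_sequence()].
#' @seealso [format_sequence()], [read_sequences()]
#' @export
parse_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("empty sequence string", call. = FALSE)
  parts <- strsplit(s, "(1-4)", fixed = TRUE)[[1]]
  parts <- unlist(strsplit(parts, "(1->4)", fixed = TRUE), use.names = FALSE)
  aglycone <- "free"
  last <- parts[length(parts)]
  if (grepl("-pNA-N3$", last)) {
    aglycone <- "pNA-N3"
    parts[length(parts)] <- sub("-pNA-N3$", "", last)
  } else if (grepl("-pNP$", last)) {
    aglycone <- "pNP"
    parts[length(parts)] <- sub("-pNP$", "", last)
  }
  if (any(!nzchar(parts)))
    stop("malformed sequence string: '", text, "'", call. = FALSE)
  hs_oligo_from_tokens(parts, aglycone)
}

#' Format an oligosaccharide as its canonical sequence string
#'
#' @param oligo an `hs_oligo`.
#' @return character scalar; `parse_sequence(format_sequence(x))` is
#'   identical to `x`.
#' @export
format_sequence <- function(oligo) {
  stopifnot(inherits(oligo, "hs_oligo"))
  s <- paste(oligo$tokens, collapse = "(1-4)")
  if (oligo$aglycone != "free") s <- paste0(s, "-", oligo$aglycone)
  s
}

#' @export
format.hs_oligo <- function(x, ...) format_sequence(x)

#' @export
print.hs_oligo <- function(x, ...) {
  n <- length(x$tokens)
  cat("<hs_oligo> ", .chain_size_name(n), ", aglycone ", x$aglycone, "\n",
      sep = "")
  cat("  ", format_sequence(x), "\n", sep = "")
  lab <- residue_labels(x)
  cat("  labels: ", paste0(lab, "=", x$tokens, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.chain_size_name <- function(n) {
  nm <- c("monosaccharide", "disaccharide", "trisaccharide",
          "tetrasaccharide", "pentasaccharide", "hexasaccharide",
          "heptasaccharide", "octasaccharide", "nonasaccharide",
          "decasaccharide")
  if (n <= length(nm)) nm[n] else paste0(n, "-mer")
}

#' Residue objects of a chain
#'
#' @param oligo an `hs_oligo`.
#' @return list of `hs_residue` objects, non-reducing to reducing end.
#' @export
residues <- function(oligo) {
  stopifnot(inherits(oligo, "hs_oligo"))
  lapply(oligo$tokens, parse_residue)
}

#' @export
`==.hs_oligo` <- function(e1, e2) {
  identical(format_sequence(e1), format_sequence(e2))
}

# motif search --------------------------------------------------------------

.AT_PATTERN <- c("GlcNS6S", "GlcA", "GlcNS3S6S", "IdoA2S", "GlcNS6S")

#' Locate the antithrombin-binding pentasaccharide motif
#'
#' Scans all 5-residue windows for the antithrombin III binding sequence
#' GlcNS6S-GlcA-GlcNS3S6S-IdoA2S-GlcNS6S (non-reducing to reducing end),
#' the structural determinant of heparin's anticoagulant activity.
#' Overlapping hits are all reported.
#'
#' @param oligo an `hs_oligo`.
#' @return data.frame with columns `start_label`, `end_label`, `start`,
#'   `end` (residue indices); zero rows when the motif is absent.
#' @examples
#' find_at_motif(get_fixture("14")$oligo)
#' @export
find_at_motif <- function(oligo) {
  stopifnot(inherits(oligo, "hs_oligo"))
  tok <- oligo$tokens
  lab <- residue_labels(oligo)
  k <- length(.AT_PATTERN)
  hits <- integer()
  if (length(tok) >= k) {
    for (i in seq_len(length(tok) - k + 1L)) {
      if (all(tok[i:(i + k - 1L)] == .AT_PATTERN)) hits <- c(hits, i)
    }
  }
  data.frame(
    start_label = lab[hits], end_label = lab[hits + k - 1L],
    start = hits, end = hits + k - 1L,
    stringsAsFactors = FALSE
  )
}

# sulfation statistics ------------------------------------------------------

#' Sulfation statistics of a chain
#'
#' Counts sulfo groups by position class and summarizes the chain the way
#' heparin/HS bulk composition is reported: sulfo groups per disaccharide
#' unit and the IdoA share of uronic residues (heparin averages about 2.6
#' sulfo groups and 80-90% IdoA per disaccharide; typical HS about 0.6
#' and 20%).
#'
#' @param oligo an `hs_oligo`.
#' @return list of class `hs_sulfation_stats`: counts `n_sulfo` (N-sulfo),
#'   `o2_sulfo`, `o3_sulfo`, `o6_sulfo`, `total_sulfo`,
#'   `sulfo_per_disaccharide` (total / (residues/2)) and
#'   `pct_idoA_of_uronic`.
#' @export
sulfation_stats <- function(oligo) {
  stopifnot(inherits(oligo, "hs_oligo"))
  res <- residues(oligo)
  n_s <- sum(vapply(res, function(r) r$n_sub == "sulfo", NA))
  o2 <- sum(vapply(res, function(r) 2L %in% r$o_sulfo, NA))
  o3 <- sum(vapply(res, function(r) 3L %in% r$o_sulfo, NA))
  o6 <- sum(vapply(res, function(r) 6L %in% r$o_sulfo, NA))
  uronic <- vapply(res, function(r) r$ring != .RING_GLCN, NA)
  ido <- vapply(res, function(r) r$ring == .RING_IDOA, NA)
  total <- n_s + o2 + o3 + o6
  structure(list(
    n_sulfo = n_s, o2_sulfo = o2, o3_sulfo = o3, o6_sulfo = o6,
    total_sulfo = total,
    sulfo_per_disaccharide = total / (length(res) / 2),
    pct_idoA_of_uronic = if (any(uronic)) 100 * sum(ido) / sum(uronic) else NA_real_
  ), class = "hs_sulfation_stats")
}

#' @export
print.hs_sulfation_stats <- function(x, ...) {
  cat("Sulfation: total", x$total_sulfo,
      sprintf("(N:%d, 2-O:%d, 3-O:%d, 6-O:%d)", x$n_sulfo, x$o2_sulfo,
              x$o3_sulfo, x$o6_sulfo), "\n")
  cat(sprintf("  %.2f sulfo groups per disaccharide; %.1f%% IdoA of uronic\n",
              x$sulfo_per_disaccharide, x$pct_idoA_of_uronic))
  invisible(x)
}

# sequence files -------------------------------------------------------------

#' Read sequences from a plain-text file
#'
#' One sequence per line; blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return list of `hs_oligo`.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lapply(lines[nzchar(lines)], parse_sequence)
}
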