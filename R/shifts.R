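# Context-dependent anomeric chemical-shift prediction.
#
# The anomeric 1H/13C shift of a residue in these chains is determined
# almost entirely by the residue's own identity and by the residue on its
# REDUCING side (steric interaction across the glycosidic bond); the
# non-reducing neighbor has minimal influence. The model is therefore a
# lookup keyed on (residue class, reducing-side context class).

.shift_cache <- new.env(parent = emptyenv())

#' The anomeric shift model table
#'
#' Loads the versioned model table shipped with the package (or a
#' user-supplied replacement in the same CSV format).
#'
#' @param path optional path to an alternative model CSV with columns
#'   `residue`, `context`, `delta_h`, `tol_h`, `delta_c`, `tol_c`
#'   (`#` comment lines allowed; empty `delta_c` means no established
#'   13C value).
#' @return data.frame, one row per (residue, context) entry.
#' @export
shift_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.shift_cache$tab)) return(.shift_cache$tab)
    path <- system.file("extdata", "shift_table.csv", package = "hsoligo",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .shift_cache$tab <- tab
    return(tab)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Resolve the context class of residue i within the chain.
.context_class <- function(oligo, i) {
  tok <- oligo$tokens
  n <- length(tok)
  if (i < n) {
    nb <- parse_residue(tok[i + 1L])
    this_uronic <- .tok_is_uronic(tok[i])
    if (!this_uronic) {
      # glucosamine: context is the uronic neighbor's ring family
      if (nb$ring == .RING_GLCA) "GlcA-neighbor" else "IdoA-neighbor"
    } else {
      # uronic: context is the glucosamine neighbor's substitution class
      if (!nb$n_sub %in% c("acetyl", "sulfo")) return(NA_character_)
      if (6L %in% nb$o_sulfo) "GlcNX6S-neighbor" else "GlcNX-neighbor"
    }
  } else {
    if (oligo$aglycone == "pNA-N3") "aglycone-pNA" else NA_character_
  }
}

#' Predict anomeric shifts for every residue of a chain
#'
#' For each residue the reducing-side neighbor (or the aglycone, for the
#' reducing-end residue) selects the model row; the prediction is that
#' row's 1H (and, when established, 13C) shift, together with the
#' J-coupling class implied by the residue's anomeric configuration.
#' IdoA2S predictions are flagged `"broad"`: the anomeric signal of
#' 2-O-sulfo-iduronate is broadened by ring-conformer exchange.
#'
#' @param oligo an `hs_oligo`.
#' @param model model table as returned by [shift_table()].
#' @param partial if `FALSE` (default), an unresolved (residue, context)
#'   combination is an error naming the offending residues; if `TRUE`,
#'   unresolved residues are returned with `NA` shifts and the
#'   `"unresolved"` note.
#' @return data.frame of class `hs_shifts` with one row per residue:
#'   `label`, `residue`, `context`, `delta_h`, `delta_c`, `j_hz`,
#'   `j_class`, `note`.
#' @examples
#' predict_shifts(get_fixture("14")$oligo)
#' @export
predict_shifts <- function(oligo, model = shift_table(), partial = FALSE) {
  stopifnot(inherits(oligo, "hs_oligo"))
  tok <- oligo$tokens
  lab <- residue_labels(oligo)
  n <- length(tok)
  ctx <- vapply(seq_len(n), function(i) .context_class(oligo, i), "")
  dh <- dc <- rep(NA_real_, n)
  note <- character(n)
  for (i in seq_len(n)) {
    if (is.na(ctx[i])) { note[i] <- "unresolved"; next }
    row <- which(model$residue == tok[i] & model$context == ctx[i])
    if (length(row) != 1L) { note[i] <- "unresolved"; next }
    dh[i] <- model$delta_h[row]
    dc[i] <- model$delta_c[row]
    if (tok[i] == "IdoA2S") note[i] <- "broad"
  }
  if (!partial && any(note == "unresolved")) {
    bad <- which(note == "unresolved")
    stop("no model entry for residue(s) ",
         paste0(lab[bad], " (", tok[bad], " | ",
                ifelse(is.na(ctx[bad]), "no resolvable context", ctx[bad]),
                ")", collapse = ", "),
         call. = FALSE)
  }
  jc <- vapply(tok, function(t) j_class(parse_residue(t))$class, "")
  out <- data.frame(
    label = lab, residue = tok, context = ctx,
    delta_h = dh, delta_c = dc,
    j_hz = ifelse(jc == "alpha", 4, 8), j_class = jc, note = note,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("hs_shifts", "data.frame")
  out
}

#' @export
print.hs_shifts <- function(x, ...) {
  cat("Predicted anomeric shifts (1H/13C, D2O 298 K)\n")
  df <- as.data.frame(x)
  df$delta_h <- sprintf("%.2f", df$delta_h)
  df$delta_c <- ifelse(is.na(df$delta_c), "-", sprintf("%.1f", df$delta_c))
  df$j <- sprintf("~%d Hz (%s)", df$j_hz, df$j_class)
  print(df[, c("label", "residue", "context", "delta_h", "delta_c", "j",
               "note")], row.names = FALSE)
  invisible(x)
}

#' Anomeric J-coupling class of a residue
#'
#' The 3J(H1,H2) coupling constant reports the anomeric configuration:
#' about 4 Hz for alpha-linked residues (glucosamine, iduronate) and
#' about 8 Hz for beta-linked glucuronate.
#'
#' @param residue an `hs_residue` (or a residue token string).
#' @return list with `class` (`"alpha"`/`"beta"`) and `j_hz` (4 or 8).
#' @examples
#' j_class("GlcNS6S")  # ~4 Hz, alpha
#' j_class("GlcA")     # ~8 Hz, beta
#' @export
j_class <- function(residue) {
  if (is.character(residue)) residue <- parse_residue(residue)
  stopifnot(inherits(residue, "hs_residue"))
  if (residue$anomeric_config == "alpha") list(class = "alpha", j_hz = 4)
  else list(class = "beta", j_hz = 8)
}

#' Number of anomeric signals expected in the 1H spectrum
#'
#' Each ring contributes exactly one anomeric proton, so the count of
#' resolved anomeric signals reports the chain length (six signals
#' confirm a hexasaccharide).
#'
#' @param oligo an `hs_oligo`.
#' @return integer.
#' @export
count_anomeric_signals <- function(oligo) {
  stopifnot(inherits(oligo, "hs_oligo"))
  length(oligo$tokens)
}
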