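# Named compounds of the library: the seed acceptor, the seven key
# synthesis intermediates I-VII and the characterized library members
# 14, 28, 46, 65 and 66.

.fixture_cache <- new.env(parent = emptyenv())

.fixture_table <- function() {
  if (!is.null(.fixture_cache$tab)) return(.fixture_cache$tab)
  path <- system.file("extdata", "fixtures.tsv", package = "hsoligo",
                      mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tab <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    flag = vapply(parts, `[`, "", 2L),
    sequence = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  .fixture_cache$tab <- tab
  tab
}

#' Retrieve a named library compound
#'
#' Returns one of the package's built-in structures: the monosaccharide
#' seed acceptor (`"seed"`), the key synthesis intermediates `"I"` to
#' `"VII"`, or library compounds `"14"`, `"28"`, `"46"`, `"65"`, `"66"`.
#'
#' @param name compound identifier (character).
#' @return list with elements `oligo` (an [hs_oligo][parse_sequence]),
#'   `name`, and `flag`: `"printed"` when the structure is stated
#'   verbatim in the source characterization, `"reconstructed"` when it
#'   is inferred from the synthesis-route logic (see the vignette for the
#'   reconstruction arguments).
#' @examples
#' get_fixture("14")
#' @export
get_fixture <- function(name) {
  tab <- .fixture_table()
  name <- as.character(name)
  i <- match(name, tab$name)
  if (is.na(i))
    stop("unknown compound name: '", name, "' (known: ",
         paste(tab$name, collapse = ", "), ")", call. = FALSE)
  list(name = name, oligo = parse_sequence(tab$sequence[i]), flag = tab$flag[i])
}

#' Names of all built-in compounds
#'
#' @return character vector of fixture names.
#' @export
fixture_names <- function() .fixture_table()$name
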