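# File formats and the command-line entry point.

#' Read a peak-list CSV
#'
#' Expected header: `ppm_h` (required), optional `ppm_c`, `j_hz`. Empty
#' cells become NA. Malformed rows are reported with their line number.
#'
#' @param path CSV file path.
#' @return an [hs_peaklist()].
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"ppm_h" %in% names(df))
    stop("peak-list CSV must have a ppm_h column: ", path, call. = FALSE)
  bad <- which(is.na(suppressWarnings(as.numeric(df$ppm_h))))
  if (length(bad))
    stop("malformed ppm_h value at data line ", bad[1L], " of ", path,
         call. = FALSE)
  hs_peaklist(as.numeric(df$ppm_h),
              if ("ppm_c" %in% names(df)) as.numeric(df$ppm_c) else NULL,
              if ("j_hz" %in% names(df)) as.numeric(df$j_hz) else NULL)
}

#' Write a tabular report
#'
#' @param result a data.frame (or object coercible to one).
#' @param path output file path.
#' @param format `"tsv"` (values formatted: ppm to 2 decimals, Da to 1)
#'   or `"json"` (full precision). Both carry identical values up to
#'   the stated formatting.
#' @return invisibly, `path`.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(result)
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    out <- df
    for (nm in names(out)) {
      if (is.numeric(out[[nm]])) {
        digits <- if (grepl("ppm|delta|d_h|d_c", nm)) 2L
                  else if (grepl("mass|mz|Da", nm)) 1L else NA_integer_
        if (!is.na(digits))
          out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                              formatC(out[[nm]], digits = digits,
                                      format = "f"))
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

.cli_usage <- function() {
  paste(
    "usage: hsoligo <command> [options]",
    "commands:",
    "  parse     --seq <string>                 validate and describe a sequence",
    "  mass      --seq <string>                 formula, average & monoisotopic mass",
    "  mz        --mass <Da> --charges 4,5,6    negative-mode ESI ladder",
    "  shifts    --seq <string>                 predicted anomeric shifts",
    "  assign    --seq <string> --peaks <csv> [--partial]  peak assignment",
    "  motif     --seq <string>                 AT pentasaccharide motif hits",
    "  stats     --seq <string>                 sulfation statistics",
    "  plan      --target <seq> [--seed-seq <seq>] [--max-steps N]",
    "  enumerate [--seed-seq <seq>] --max-steps N",
    "  simulate  --seq <string> [--sigma-h s] [--seed N] [--n N]",
    "common: --out <path> --format tsv|json (default: TSV to stdout)",
    sep = "\n")
}

.cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (key %in% c("mono", "partial")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(argv)) stop("missing value for --", key, call. = FALSE)
      opts[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.cli_emit <- function(df, opts) {
  format <- if (!is.null(opts$format)) opts$format else "tsv"
  if (!is.null(opts$out)) {
    write_report(df, opts$out, format)
  } else {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    write_report(df, tmp, format)
    writeLines(readLines(tmp, warn = FALSE))
  }
}

#' Command-line dispatcher
#'
#' Backs the `inst/cli/hsoligo.R` script:
#' `Rscript -e 'quit(status = hsoligo::hsoligo_main(commandArgs(TRUE)))'`.
#' See `hsoligo_main(character(0))` for the subcommand list.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code: 0 on success, 2 on usage or validation
#'   error (the error message is printed to stderr).
#' @export
hsoligo_main <- function(argv) {
  run <- function() {
    if (length(argv) == 0L) stop(.cli_usage(), call. = FALSE)
    cmd <- argv[1L]
    opts <- .cli_args(argv[-1L])
    need <- function(key) {
      if (is.null(opts[[key]]))
        stop("command '", cmd, "' requires --", key, call. = FALSE)
      opts[[key]]
    }
    switch(cmd,
      parse = {
        o <- parse_sequence(need("seq"))
        .cli_emit(data.frame(label = residue_labels(o), residue = o$tokens,
                             aglycone = o$aglycone), opts)
      },
      mass = {
        m <- oligo_mass(parse_sequence(need("seq")))
        .cli_emit(data.frame(formula = m$formula, average_mass = m$average,
                             monoisotopic_mass = m$monoisotopic), opts)
      },
      mz = {
        charges <- as.integer(strsplit(need("charges"), ",")[[1]])
        .cli_emit(esi_ladder(as.numeric(need("mass")), charges), opts)
      },
      shifts = .cli_emit(predict_shifts(parse_sequence(need("seq"))), opts),
      assign = {
        o <- parse_sequence(need("seq"))
        pk <- read_peaklist(need("peaks"))
        mode <- if (isTRUE(opts$partial)) "partial" else "strict"
        .cli_emit(assign_peaks(o, pk, mode = mode)$table, opts)
      },
      motif = .cli_emit(find_at_motif(parse_sequence(need("seq"))), opts),
      stats = {
        s <- sulfation_stats(parse_sequence(need("seq")))
        .cli_emit(as.data.frame(unclass(s)), opts)
      },
      plan = {
        seed <- parse_sequence(
          if (!is.null(opts[["seed-seq"]])) opts[["seed-seq"]]
          else "GlcA-pNA-N3")
        ctl <- planner_control(
          max_steps = if (!is.null(opts[["max-steps"]]))
            as.integer(opts[["max-steps"]]) else 20L)
        rt <- plan_route(seed, parse_sequence(need("target")), ctl)
        if (!rt$feasible) stop(rt$reason, call. = FALSE)
        .cli_emit(rt$steps, opts)
      },
      enumerate = {
        seed <- parse_sequence(
          if (!is.null(opts[["seed-seq"]])) opts[["seed-seq"]]
          else "GlcA-pNA-N3")
        seqs <- enumerate_library(seed, as.integer(need("max-steps")))
        .cli_emit(data.frame(sequence = seqs), opts)
      },
      simulate = {
        cfg <- sim_config(
          noise_sigma_h = if (!is.null(opts[["sigma-h"]]))
            as.numeric(opts[["sigma-h"]]) else 0.02,
          rng_seed = if (!is.null(opts$seed)) as.integer(opts$seed) else 1L)
        sim <- simulate_peaklist(parse_sequence(need("seq")), cfg)
        out <- as.data.frame(sim$peaks)
        out$true_label <- sim$truth$label[match(seq_len(nrow(out)),
                                                sim$truth$peak)]
        .cli_emit(out, opts)
      },
      stop("unknown command '", cmd, "'\n", .cli_usage(), call. = FALSE)
    )
    0L
  }
  tryCatch(run(), error = function(e) {
    message(conditionMessage(e))
    2L
  })
}
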