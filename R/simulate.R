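# Synthetic anomeric peak lists and random valid sequences.
#
# The simulator emulates what an anomeric-region read-out of a clean 1D
# spectrum of a pure compound provides: one (1H, 13C) pair per residue,
# centered on the shift-model prediction with Gaussian measurement
# scatter on the scale of the model's stated dispersions (a few
# hundredths of a ppm in 1H, a few tenths in 13C). It does not model
# lineshape, signal overlap, or solvent/temperature effects.

#' Simulation settings
#'
#' @param noise_sigma_h Gaussian standard deviation of the 1H shifts
#'   (ppm). Default 0.02, mid-range of the model's stated dispersions.
#' @param noise_sigma_c same for 13C (ppm); default 0.2.
#' @param dropout_rate fraction of peaks omitted, in `[0, 1)`; emulates
#'   unresolved or unobserved signals.
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return list of class `hs_sim_config`.
#' @export
sim_config <- function(noise_sigma_h = 0.02, noise_sigma_c = 0.2,
                       dropout_rate = 0, rng_seed = 1L) {
  stopifnot(noise_sigma_h >= 0, noise_sigma_c >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(noise_sigma_h = noise_sigma_h, noise_sigma_c = noise_sigma_c,
                 dropout_rate = dropout_rate, rng_seed = as.integer(rng_seed)),
            class = "hs_sim_config")
}

#' Simulate a noisy anomeric peak list
#'
#' Draws one peak per residue around the predicted shifts, shuffles the
#' rows, and optionally drops a fraction of peaks, returning the
#' ground-truth residue-to-peak mapping alongside.
#'
#' @param oligo an `hs_oligo` on which [predict_shifts()] succeeds.
#' @param config an [sim_config()].
#' @param model shift model table.
#' @return list with `peaks` (an [hs_peaklist()]), `truth` (data.frame
#'   `label`, `peak`: the row of `peaks` emitted by each residue, NA for
#'   dropped peaks) and `shifts` (the underlying predictions).
#' @examples
#' simulate_peaklist(get_fixture("14")$oligo, sim_config(rng_seed = 7))
#' @export
simulate_peaklist <- function(oligo, config = sim_config(),
                              model = shift_table()) {
  stopifnot(inherits(config, "hs_sim_config"))
  pred <- predict_shifts(oligo, model = model)
  n <- nrow(pred)
  set.seed(config$rng_seed)
  ppm_h <- pred$delta_h + stats::rnorm(n, 0, config$noise_sigma_h)
  ppm_c <- ifelse(is.na(pred$delta_c), NA_real_,
                  pred$delta_c + stats::rnorm(n, 0, config$noise_sigma_c))
  ord <- sample.int(n)                       # residue emitting each row
  keep_rows <- seq_len(n)
  if (config$dropout_rate > 0) {
    n_drop <- floor(config$dropout_rate * n)
    if (n_drop > 0) keep_rows <- sort(sample.int(n, n - n_drop))
  }
  peaks <- hs_peaklist(ppm_h[ord][keep_rows], ppm_c[ord][keep_rows],
                       allow_duplicates = TRUE)
  # truth: residue ord[keep_rows[k]] emitted row k
  truth_peak <- rep(NA_integer_, n)
  truth_peak[ord[keep_rows]] <- seq_along(keep_rows)
  list(peaks = peaks,
       truth = data.frame(label = pred$label, peak = truth_peak,
                          stringsAsFactors = FALSE),
       shifts = pred)
}

#' Monte-Carlo assignment recovery rate
#'
#' Simulates `n_replicates` noisy peak lists for `oligo`, assigns each
#' with [assign_peaks()], and reports the fraction in which the true
#' assignment is recovered. Recovery is judged up to exchange of
#' spectroscopically indistinguishable residues: residues with identical
#' predicted 1H, 13C and J-class (e.g. two GlcNS6S residues both in GlcA
#' context) cannot be told apart by any assignment method, so mapping a
#' peak to either member of such a class counts as correct. When all
#' predictions are distinct this reduces to exact recovery.
#'
#' @param oligo an `hs_oligo`.
#' @param n_replicates number of simulated spectra.
#' @param config an [sim_config()]; its `rng_seed` seeds the whole run
#'   (replicate r uses `rng_seed + r - 1`).
#' @param model shift model table.
#' @param control assignment cost parameters.
#' @return fraction in `[0, 1]` of replicates fully recovered.
#' @export
assignment_recovery <- function(oligo, n_replicates = 200,
                                config = sim_config(),
                                model = shift_table(),
                                control = assign_control()) {
  pred <- predict_shifts(oligo, model = model)
  sig <- paste(pred$delta_h, pred$delta_c, pred$j_class)
  ok <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + r - 1L
    sim <- simulate_peaklist(oligo, cfg, model = model)
    mode <- if (nrow(sim$peaks) == nrow(pred)) "strict" else "partial"
    asg <- assign_peaks(oligo, sim$peaks, mode = mode, model = model,
                        control = control)
    # recovered iff every assigned peak maps to a residue whose predicted
    # signature equals that of the residue that truly emitted it
    truth_residue <- match(seq_len(nrow(sim$peaks)), sim$truth$peak)
    got_residue <- match(seq_len(nrow(sim$peaks)), asg$table$peak)
    if (all(!is.na(got_residue)) &&
        all(sig[got_residue] == sig[truth_residue])) ok <- ok + 1L
  }
  ok / n_replicates
}

#' Draw a random valid sequence
#'
#' Generates a chain with strictly alternating ring classes, residue
#' states drawn uniformly from the legal vocabulary (3-O-sulfation only
#' on N-sulfated glucosamines by construction). With
#' `reachable_only = TRUE` the draw is restricted to structures the
#' enzyme set can actually make, by sampling from
#' [enumerate_library()] output of the matching length.
#'
#' @param length chain length (>= 1).
#' @param rng_seed integer seed.
#' @param first_ring ring class of the non-reducing-end residue:
#'   `"uronic"` (default, as in all library compounds, which run
#'   uronic-...-uronic onto the aglycone) or `"glucosamine"`.
#' @param aglycone reducing-end tag.
#' @param reachable_only restrict to enzymatically reachable structures
#'   (requires `first_ring = "uronic"` parity such that the reducing end
#'   is a GlcA; an error if no reachable structure has the requested
#'   length).
#' @param control planner rules, used when `reachable_only = TRUE`.
#' @return an `hs_oligo`.
#' @export
random_sequence <- function(length, rng_seed = 1L,
                            first_ring = c("uronic", "glucosamine"),
                            aglycone = "pNA-N3", reachable_only = FALSE,
                            control = planner_control()) {
  stopifnot(length >= 1)
  first_ring <- match.arg(first_ring)
  set.seed(rng_seed)
  if (reachable_only) {
    seed <- hs_oligo_from_tokens("GlcA", aglycone)
    # depth bound: length-1 elongations plus a sulfation/epimerization budget
    pool <- enumerate_library(seed, max_steps = (length - 1L) + 4L,
                              control = control)
    pool <- pool[vapply(pool, function(s)
      base::length(parse_sequence(s)$tokens), 0L) == length]
    if (base::length(pool) == 0L)
      stop("no enzymatically reachable structure of length ", length,
           call. = FALSE)
    return(parse_sequence(sample(pool, 1L)))
  }
  uronic_pool <- c("GlcA", "GlcA2S", "IdoA", "IdoA2S")
  glcn_pool <- c("GlcN", "GlcNAc", "GlcNAc6S", "GlcNTFA", "GlcNS",
                 "GlcNS6S", "GlcNS3S", "GlcNS3S6S")
  tokens <- character(length)
  is_uronic_pos <- if (first_ring == "uronic")
    (seq_len(length) %% 2L) == 1L else (seq_len(length) %% 2L) == 0L
  tokens[is_uronic_pos] <- sample(uronic_pool, sum(is_uronic_pos),
                                  replace = TRUE)
  tokens[!is_uronic_pos] <- sample(glcn_pool, sum(!is_uronic_pos),
                                   replace = TRUE)
  hs_oligo_from_tokens(tokens, aglycone)
}
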