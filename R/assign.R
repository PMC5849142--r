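# Assignment of observed anomeric peaks to the residues of a candidate
# sequence, by cost-minimizing bipartite matching against the predicted
# shifts. This formalizes the manual reasoning used when assigning these
# spectra: each observed anomeric signal is attributed to the residue
# whose expected shift (and J multiplicity) it matches best, with every
# signal used at most once.

#' Construct a peak list
#'
#' @param ppm_h numeric vector of anomeric 1H shifts (required; all in
#'   the anomeric window 3.0-6.5 ppm).
#' @param ppm_c optional numeric vector of 13C shifts (NA allowed).
#' @param j_hz optional numeric vector of 3J(H1,H2) values in Hz (NA
#'   allowed).
#' @param allow_duplicates by default rows duplicated after rounding to
#'   0.001 ppm are rejected (a picked peak appears once); set `TRUE` for
#'   lists where coincident rows are legitimate, e.g. noise-free
#'   simulations of chains with spectroscopically equivalent residues.
#' @return data.frame of class `hs_peaklist` with columns `ppm_h`,
#'   `ppm_c`, `j_hz`.
#' @export
hs_peaklist <- function(ppm_h, ppm_c = NULL, j_hz = NULL,
                        allow_duplicates = FALSE) {
  stopifnot(is.numeric(ppm_h), length(ppm_h) >= 1L)
  n <- length(ppm_h)
  if (is.null(ppm_c)) ppm_c <- rep(NA_real_, n)
  if (is.null(j_hz)) j_hz <- rep(NA_real_, n)
  stopifnot(length(ppm_c) == n, length(j_hz) == n)
  if (any(ppm_h < 3.0 | ppm_h > 6.5))
    stop("ppm_h outside the anomeric window [3.0, 6.5]", call. = FALSE)
  key <- paste(round(ppm_h, 3), round(ppm_c, 3), round(j_hz, 3))
  if (!allow_duplicates && anyDuplicated(key))
    stop("duplicate peak rows (after rounding to 0.001 ppm)", call. = FALSE)
  out <- data.frame(ppm_h = as.numeric(ppm_h), ppm_c = as.numeric(ppm_c),
                    j_hz = as.numeric(j_hz))
  class(out) <- c("hs_peaklist", "data.frame")
  out
}

#' Matching cost parameters
#'
#' @param w_c weight of the 13C deviation relative to 1H, per ppm. 13C
#'   anomeric dispersions are roughly ten times the 1H ones, hence the
#'   default 0.1.
#' @param j_penalty fixed cost (in ppm-equivalents) for pairing a peak
#'   whose measured J implies one anomeric configuration with a residue
#'   of the other; near-disqualifying by default.
#' @param tol_h,tol_c deviations beyond these (ppm) are flagged as
#'   out-of-tolerance in the report.
#' @return list of class `hs_assign_control`.
#' @export
assign_control <- function(w_c = 0.1, j_penalty = 1.0, tol_h = 0.05,
                           tol_c = 0.5) {
  stopifnot(w_c >= 0, j_penalty >= 0, tol_h > 0, tol_c > 0)
  structure(list(w_c = w_c, j_penalty = j_penalty, tol_h = tol_h,
                 tol_c = tol_c), class = "hs_assign_control")
}

# pair cost between predicted residue shifts (row of hs_shifts) and one peak
.pair_cost <- function(dh, dc, jc, ppm_h, ppm_c, j_hz, control) {
  cost <- abs(dh - ppm_h)
  if (!is.na(dc) && !is.na(ppm_c)) cost <- cost + control$w_c * abs(dc - ppm_c)
  if (!is.na(j_hz) && j_hz != 6) {
    peak_class <- if (j_hz < 6) "alpha" else "beta"
    if (peak_class != jc) cost <- cost + control$j_penalty
  }
  cost
}

# all permutations of 1..n, in lexicographic order (n <= 8 in practice)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}

# O(n^3) Hungarian algorithm (shortest augmenting paths with potentials);
# rows = residues, columns = peaks; returns for each row its column.
.solve_lap <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)
  v <- numeric(n + 1L)            # index n+1 is the virtual start column
  p <- integer(n + 1L)            # row matched to each column (0 = none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) ans[p[j]] <- j
  ans
}

#' Assign observed anomeric peaks to the residues of a sequence
#'
#' Finds the peak-to-residue mapping minimizing the total cost
#' \eqn{\sum |\Delta\delta_H| + w_C |\Delta\delta_C| + J\text{-mismatch}}
#' over all bijections (strict mode) or injections of peaks into
#' residues (partial mode, for spectra where some signals are
#' unresolved). Instances with at most eight residues are solved by
#' exhaustive enumeration over all bijections, larger ones by an optimal
#' linear-assignment (Hungarian) solver; ties in strict mode resolve to
#' the lexicographically first assignment in residue-label order.
#'
#' @param oligo candidate `hs_oligo`.
#' @param peaks an [hs_peaklist()] (a plain data.frame with the same
#'   columns is accepted). At most as many rows as residues.
#' @param mode `"strict"` requires exactly one peak per residue;
#'   `"partial"` allows fewer peaks and leaves the remaining residues
#'   unassigned.
#' @param model shift model table, see [shift_table()].
#' @param control cost parameters, see [assign_control()].
#' @return object of class `hs_assignment`: a list with `table` (one row
#'   per residue: `label`, `residue`, `peak` index or NA, observed and
#'   predicted values, `d_h`/`d_c` deviations, `flag`), `total_cost` and
#'   `mode`.
#' @examples
#' cmp14 <- get_fixture("14")$oligo
#' assign_peaks(cmp14, hs_peaklist(c(4.56, 5.07)), mode = "partial")
#' @export
assign_peaks <- function(oligo, peaks, mode = c("strict", "partial"),
                         model = shift_table(), control = assign_control()) {
  mode <- match.arg(mode)
  stopifnot(inherits(oligo, "hs_oligo"), is.data.frame(peaks))
  if (!all(c("ppm_h") %in% names(peaks)))
    stop("peak list must have a ppm_h column", call. = FALSE)
  if (is.null(peaks$ppm_c)) peaks$ppm_c <- NA_real_
  if (is.null(peaks$j_hz)) peaks$j_hz <- NA_real_
  pred <- predict_shifts(oligo, model = model)
  n <- nrow(pred)
  p <- nrow(peaks)
  if (p > n)
    stop("more peaks (", p, ") than residues (", n, ")", call. = FALSE)
  if (mode == "strict" && p < n)
    stop("strict mode requires exactly ", n, " peaks; got ", p,
         " (use mode = \"partial\")", call. = FALSE)
  # square cost matrix; columns beyond the real peaks are zero-cost
  # dummies representing "unassigned"
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(p)) {
    cost[i, k] <- .pair_cost(pred$delta_h[i], pred$delta_c[i],
                             pred$j_class[i], peaks$ppm_h[k],
                             peaks$ppm_c[k], peaks$j_hz[k], control)
  }
  if (n <= 8L) {
    perms <- .permutations(n)
    costs <- apply(perms, 1L, function(pp) sum(cost[cbind(seq_len(n), pp)]))
    best <- perms[which.min(costs), ]   # first minimum = label-order tie-break
  } else {
    best <- .solve_lap(cost)
  }
  peak_idx <- ifelse(best <= p, best, NA_integer_)
  d_h <- ifelse(is.na(peak_idx), NA_real_,
                peaks$ppm_h[peak_idx] - pred$delta_h)
  d_c <- ifelse(is.na(peak_idx), NA_real_,
                peaks$ppm_c[peak_idx] - pred$delta_c)
  flag <- ifelse(!is.na(d_h) & abs(d_h) > control$tol_h, "H-out-of-tol", "")
  flag <- paste0(flag, ifelse(!is.na(d_c) & abs(d_c) > control$tol_c,
                              " C-out-of-tol", ""))
  tab <- data.frame(
    label = pred$label, residue = pred$residue, peak = peak_idx,
    ppm_h = ifelse(is.na(peak_idx), NA_real_, peaks$ppm_h[peak_idx]),
    ppm_c = ifelse(is.na(peak_idx), NA_real_, peaks$ppm_c[peak_idx]),
    pred_h = pred$delta_h, pred_c = pred$delta_c,
    d_h = d_h, d_c = d_c, flag = trimws(flag),
    stringsAsFactors = FALSE
  )
  total <- sum(cost[cbind(seq_len(n), best)])
  structure(list(table = tab, total_cost = total, mode = mode,
                 sequence = format_sequence(oligo)),
            class = "hs_assignment")
}

#' @export
print.hs_assignment <- function(x, ...) {
  cat("Peak assignment (", x$mode, " mode), total cost ",
      sprintf("%.4f", x$total_cost), "\n", sep = "")
  df <- x$table
  df$ppm_h <- ifelse(is.na(df$ppm_h), "-", sprintf("%.2f", df$ppm_h))
  df$pred_h <- sprintf("%.2f", df$pred_h)
  df$d_h <- ifelse(is.na(df$d_h), "-", sprintf("%+.3f", df$d_h))
  print(df[, c("label", "residue", "peak", "ppm_h", "pred_h", "d_h",
               "flag")], row.names = FALSE)
  invisible(x)
}

#' Rank candidate sequences against an observed peak list
#'
#' Scores each candidate by its optimal assignment cost (see
#' [assign_peaks()]) and ranks ascending — the quality-control use case:
#' which library structure best explains an observed anomeric pattern.
#' Ties are broken by the candidate's sequence string.
#'
#' @param peaks an [hs_peaklist()].
#' @param candidates non-empty list of `hs_oligo` objects.
#' @inheritParams assign_peaks
#' @return data.frame with columns `sequence`, `cost`, sorted ascending
#'   by cost.
#' @export
score_candidates <- function(peaks, candidates, mode = c("strict", "partial"),
                             model = shift_table(),
                             control = assign_control()) {
  mode <- match.arg(mode)
  if (!is.list(candidates) || length(candidates) == 0L)
    stop("candidates must be a non-empty list of hs_oligo", call. = FALSE)
  seqs <- vapply(candidates, format_sequence, "")
  costs <- vapply(candidates, function(o)
    assign_peaks(o, peaks, mode = mode, model = model,
                 control = control)$total_cost, 0)
  out <- data.frame(sequence = seqs, cost = costs, stringsAsFactors = FALSE)
  out[order(out$cost, out$sequence), , drop = FALSE]
}
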