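# Rule-based planning of chemoenzymatic synthesis routes.
#
# Actions are the enzymes used to build this library, each with its
# substrate-specificity rule encoded as an eligibility predicate on the
# current chain:
#   pmHS2+GlcNAc / pmHS2+GlcNTFA / pmHS2+GlcA  -- heparosan synthase-2
#       elongation at the NON-reducing end from the UDP-sugar donor;
#   deTFA+NST  -- chemical de-N-trifluoroacetylation followed by
#       N-sulfotransferase: every GlcNTFA -> GlcNS in one step;
#   C5-epi / C5-epi-rev -- C5-epimerase, GlcA <-> IdoA, acting only on an
#       internal unsulfated uronate flanked by two N-sulfoglucosamines
#       (the epimerization is reversible, hence the paired actions);
#   C5-epi+2-OST -- epimerase plus 2-O-sulfotransferase in one pot: the
#       transiently formed IdoA is trapped as IdoA2S, which the epimerase
#       can no longer touch (committed step);
#   2-OST-on-GlcA -- direct 2-O-sulfation of a GlcA residue (rare
#       GlcA2S product), site-selective;
#   6-OST -- 6-O-sulfation of every GlcNS/GlcNAc lacking a 6-O-sulfo;
#   3-OST-1 -- 3-O-sulfation, site-selective: requires GlcA on the
#       non-reducing side of the acceptor glucosamine, prefers sites
#       with IdoA2S on the reducing side, and by default requires the
#       acceptor to already carry a 6-O-sulfo group.
#
# All actions except 3-OST-1 and 2-OST-on-GlcA are global (one-pot,
# acting on every eligible site at once).

.ACTIONS <- c("pmHS2+GlcNAc", "pmHS2+GlcNTFA", "pmHS2+GlcA", "deTFA+NST",
              "C5-epi", "C5-epi-rev", "C5-epi+2-OST", "2-OST-on-GlcA",
              "6-OST", "3-OST-1")

.ACTION_DONOR <- c(
  "pmHS2+GlcNAc" = "UDP-GlcNAc", "pmHS2+GlcNTFA" = "UDP-GlcNTFA",
  "pmHS2+GlcA" = "UDP-GlcA", "deTFA+NST" = "PAPS", "C5-epi" = "none",
  "C5-epi-rev" = "none", "C5-epi+2-OST" = "PAPS", "2-OST-on-GlcA" = "PAPS",
  "6-OST" = "PAPS", "3-OST-1" = "PAPS")

.ACTION_MODE <- c(
  "pmHS2+GlcNAc" = "global", "pmHS2+GlcNTFA" = "global",
  "pmHS2+GlcA" = "global", "deTFA+NST" = "global", "C5-epi" = "global",
  "C5-epi-rev" = "global", "C5-epi+2-OST" = "global",
  "2-OST-on-GlcA" = "site-selective", "6-OST" = "global",
  "3-OST-1" = "site-selective")

#' Planner rule options
#'
#' @param require_6s_for_3ost should 3-OST-1 require its acceptor
#'   glucosamine to already carry a 6-O-sulfo group? Every documented use
#'   of the enzyme in this chemistry sulfates an already 6-O-sulfated
#'   GlcNS, so the default is `TRUE`.
#' @param allow_terminal_2ost may 2-OST-on-GlcA act on the
#'   aglycone-bearing reducing-terminal GlcA? Default `FALSE`.
#' @param max_steps search depth bound for [plan_route()].
#' @return list of class `hs_planner_control`.
#' @export
planner_control <- function(require_6s_for_3ost = TRUE,
                            allow_terminal_2ost = FALSE,
                            max_steps = 20L) {
  structure(list(require_6s_for_3ost = isTRUE(require_6s_for_3ost),
                 allow_terminal_2ost = isTRUE(allow_terminal_2ost),
                 max_steps = as.integer(max_steps)),
            class = "hs_planner_control")
}

#' Enzyme action catalog
#'
#' @return data.frame describing every action: `name`, `donor`
#'   (UDP-sugar or PAPS cofactor), `mode` (global or site-selective).
#' @export
enzyme_actions <- function() {
  data.frame(name = .ACTIONS, donor = unname(.ACTION_DONOR[.ACTIONS]),
             mode = unname(.ACTION_MODE[.ACTIONS]), stringsAsFactors = FALSE)
}

# eligibility on a raw token vector; returns integer site indices
.eligible_idx <- function(tok, action, control) {
  n <- length(tok)
  ns <- .tok_is_ns_class(tok)
  switch(action,
    "pmHS2+GlcNAc" = ,
    "pmHS2+GlcNTFA" = if (.tok_is_uronic(tok[1L])) 1L else integer(),
    "pmHS2+GlcA" = if (!.tok_is_uronic(tok[1L])) 1L else integer(),
    "deTFA+NST" = which(tok == "GlcNTFA"),
    "C5-epi" = ,
    "C5-epi+2-OST" = {
      i <- which(tok == "GlcA")
      i <- i[i > 1L & i < n]
      i[ns[i - 1L] & ns[i + 1L]]
    },
    "C5-epi-rev" = {
      i <- which(tok == "IdoA")
      i <- i[i > 1L & i < n]
      i[ns[i - 1L] & ns[i + 1L]]
    },
    "2-OST-on-GlcA" = {
      i <- which(tok == "GlcA")
      if (!control$allow_terminal_2ost) i <- i[i < n]
      adj <- vapply(i, function(k)
        (k > 1L && ns[k - 1L]) || (k < n && ns[k + 1L]), NA)
      i <- i[adj]
      # deterministic preference order: internal sites before terminal
      internal <- i > 1L & i < n
      c(i[internal], i[!internal])
    },
    "6-OST" = which(grepl("^GlcN(S|Ac)", tok) & !grepl("6S$", tok)),
    "3-OST-1" = {
      i <- which(ns & !grepl("3S", tok, fixed = TRUE))
      if (control$require_6s_for_3ost) i <- i[grepl("6S$", tok[i])]
      i <- i[i > 1L]
      i <- i[tok[i - 1L] == "GlcA"]
      pref <- i[i < n & tok[pmin(i + 1L, n)] == "IdoA2S"]
      if (length(pref)) pref else i
    },
    stop("unknown action: ", action, call. = FALSE)
  )
}

# apply on token vectors; sites are indices into tok; returns new tokens
.apply_idx <- function(tok, action, sites) {
  switch(action,
    "pmHS2+GlcNAc" = c("GlcNAc", tok),
    "pmHS2+GlcNTFA" = c("GlcNTFA", tok),
    "pmHS2+GlcA" = c("GlcA", tok),
    "deTFA+NST" = replace(tok, sites, "GlcNS"),
    "C5-epi" = replace(tok, sites, "IdoA"),
    "C5-epi-rev" = replace(tok, sites, "GlcA"),
    "C5-epi+2-OST" = replace(tok, sites, "IdoA2S"),
    "2-OST-on-GlcA" = replace(tok, sites, "GlcA2S"),
    "6-OST" = replace(tok, sites, paste0(tok[sites], "6S")),
    "3-OST-1" = replace(tok, sites, sub("^GlcNS", "GlcNS3S", tok[sites])),
    stop("unknown action: ", action, call. = FALSE)
  )
}

#' Residues eligible for an enzyme action
#'
#' Evaluates the substrate-specificity rule of `action` against the
#' current chain. An empty result means the enzyme is inapplicable.
#'
#' @param oligo an `hs_oligo`.
#' @param action action name, one of `enzyme_actions()$name`.
#' @param control rule options, see [planner_control()].
#' @return character vector of eligible residue labels (for elongations,
#'   the non-reducing terminal label). For 3-OST-1 the preference rule
#'   (IdoA2S on the reducing side) is already applied; for 2-OST-on-GlcA
#'   sites are ordered internal-first.
#' @examples
#' eligible_sites(get_fixture("IV")$oligo, "C5-epi")  # the middle GlcA
#' @export
eligible_sites <- function(oligo, action, control = planner_control()) {
  stopifnot(inherits(oligo, "hs_oligo"))
  action <- match.arg(action, .ACTIONS)
  idx <- .eligible_idx(oligo$tokens, action, control)
  residue_labels(oligo)[idx]
}

#' Apply an enzyme action to a chain
#'
#' @inheritParams eligible_sites
#' @param sites residue labels to act on. Global actions default to the
#'   full eligible set; site-selective actions (3-OST-1, 2-OST-on-GlcA)
#'   default to all (preference-filtered) eligible sites. Requesting an
#'   ineligible site is an error, as is applying an inapplicable action.
#' @return the transformed, validated `hs_oligo`. Elongations prepend a
#'   residue at the non-reducing end (all labels shift by one);
#'   modification actions preserve chain length.
#' @examples
#' iv <- get_fixture("IV")$oligo
#' apply_action(iv, "C5-epi+2-OST")           # -> intermediate VI
#' apply_action(iv, "2-OST-on-GlcA", "C")     # -> compound 65
#' @export
apply_action <- function(oligo, action, sites = NULL,
                         control = planner_control()) {
  stopifnot(inherits(oligo, "hs_oligo"))
  action <- match.arg(action, .ACTIONS)
  lab <- residue_labels(oligo)
  elig <- .eligible_idx(oligo$tokens, action, control)
  if (length(elig) == 0L)
    stop("action ", action, " is not applicable to ",
         format_sequence(oligo), call. = FALSE)
  if (is.null(sites)) {
    idx <- elig
  } else {
    idx <- match(sites, lab)
    if (anyNA(idx) || !all(idx %in% elig))
      stop("ineligible site(s) for ", action, ": ",
           paste(sites[is.na(idx) | !(idx %in% elig)], collapse = ", "),
           call. = FALSE)
  }
  hs_oligo_from_tokens(.apply_idx(oligo$tokens, action, idx),
                       oligo$aglycone)
}

# successor states of a token-vector state; returns list of
# list(action, sites (indices), tokens)
.successors <- function(tok, control) {
  out <- list()
  for (a in .ACTIONS) {
    elig <- .eligible_idx(tok, a, control)
    if (length(elig) == 0L) next
    if (.ACTION_MODE[[a]] == "global") {
      out[[length(out) + 1L]] <-
        list(action = a, sites = elig, tokens = .apply_idx(tok, a, elig))
    } else {
      for (s in elig) {
        out[[length(out) + 1L]] <-
          list(action = a, sites = s, tokens = .apply_idx(tok, a, s))
      }
    }
  }
  out
}

.state_key <- function(tok) paste(tok, collapse = ".")

#' Plan a chemoenzymatic route
#'
#' Breadth-first search over chain states from `seed` to `target`,
#' returning a shortest route by step count. States are deduplicated by
#' canonical sequence, which also terminates the cycles induced by the
#' reversible C5-epimerase. The action ordering is fixed, so identical
#' inputs always return the identical route.
#'
#' @param seed starting `hs_oligo` (typically the monosaccharide
#'   acceptor, `get_fixture("seed")$oligo`).
#' @param target target `hs_oligo`. Must share the seed's aglycone.
#' @param control rule options and depth bound, see [planner_control()].
#' @return object of class `hs_route`: list with `feasible`, `start`,
#'   `end`, and `steps` — a data.frame of `action`, `donor`, `sites`
#'   (comma-joined labels at application time), `product` (sequence
#'   after the step). When no route exists within `control$max_steps`,
#'   `feasible` is `FALSE` and `steps` is empty (infeasibility report).
#' @examples
#' seed <- get_fixture("seed")$oligo
#' plan_route(seed, get_fixture("IV")$oligo)
#' @export
plan_route <- function(seed, target, control = planner_control()) {
  stopifnot(inherits(seed, "hs_oligo"), inherits(target, "hs_oligo"))
  if (seed$aglycone != target$aglycone)
    stop("seed and target aglycones differ", call. = FALSE)
  target_key <- .state_key(target$tokens)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(.state_key(seed$tokens), TRUE, envir = seen)
  # each frontier node: list(tokens, path = list of steps)
  frontier <- list(list(tokens = seed$tokens, path = list()))
  found <- NULL
  if (.state_key(seed$tokens) == target_key) {
    found <- frontier[[1L]]
  } else {
    for (depth in seq_len(control$max_steps)) {
      nxt <- list()
      for (node in frontier) {
        for (succ in .successors(node$tokens, control)) {
          key <- .state_key(succ$tokens)
          if (!is.null(seen[[key]])) next
          assign(key, TRUE, envir = seen)
          step <- list(action = succ$action,
                       sites = LETTERS[succ$sites],
                       tokens = succ$tokens)
          child <- list(tokens = succ$tokens,
                        path = c(node$path, list(step)))
          if (key == target_key) { found <- child; break }
          nxt[[length(nxt) + 1L]] <- child
        }
        if (!is.null(found)) break
      }
      if (!is.null(found) || length(nxt) == 0L) break
      frontier <- nxt
    }
  }
  aglycone <- seed$aglycone
  if (is.null(found)) {
    steps <- data.frame(action = character(), donor = character(),
                        sites = character(), product = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(feasible = FALSE, start = seed, end = target,
                          steps = steps,
                          reason = paste0("no route within ",
                                          control$max_steps, " steps")),
                     class = "hs_route"))
  }
  steps <- data.frame(
    action = vapply(found$path, `[[`, "", "action"),
    donor = vapply(found$path, function(s) .ACTION_DONOR[[s$action]], ""),
    sites = vapply(found$path, function(s) paste(s$sites, collapse = ","), ""),
    product = vapply(found$path, function(s)
      format_sequence(hs_oligo_from_tokens(s$tokens, aglycone)), ""),
    stringsAsFactors = FALSE
  )
  structure(list(feasible = TRUE, start = seed, end = target, steps = steps),
            class = "hs_route")
}

#' @export
print.hs_route <- function(x, ...) {
  if (!x$feasible) {
    cat("Infeasible: ", x$reason, "\n  target: ",
        format_sequence(x$end), "\n", sep = "")
    return(invisible(x))
  }
  cat("Route (", nrow(x$steps), " steps)\n", sep = "")
  cat("  start: ", format_sequence(x$start), "\n", sep = "")
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %2d. %-14s [%s] sites %s\n      -> %s\n", i,
                x$steps$action[i], x$steps$donor[i], x$steps$sites[i],
                x$steps$product[i]))
  }
  invisible(x)
}

#' Replay and validate a route
#'
#' Re-applies every step of a route to its start state, checking
#' eligibility of the recorded sites at each intermediate state and that
#' the replay reaches the recorded end.
#'
#' @param route an `hs_route` (feasible).
#' @param control rule options used for eligibility checks.
#' @return list with `valid` (logical) and, on failure,
#'   `first_failure`: the step index and a diagnostic message.
#' @export
validate_route <- function(route, control = planner_control()) {
  stopifnot(inherits(route, "hs_route"))
  if (!route$feasible)
    return(list(valid = FALSE,
                first_failure = list(step = 0L, message = "infeasible route")))
  state <- route$start
  for (i in seq_len(nrow(route$steps))) {
    sites <- strsplit(route$steps$sites[i], ",", fixed = TRUE)[[1]]
    state <- tryCatch(
      apply_action(state, route$steps$action[i], sites, control = control),
      error = function(e)
        structure(list(step = i, message = conditionMessage(e)),
                  class = "hs_step_failure"))
    if (inherits(state, "hs_step_failure"))
      return(list(valid = FALSE, first_failure = unclass(state)))
    if (format_sequence(state) != route$steps$product[i])
      return(list(valid = FALSE, first_failure = list(
        step = i, message = "replayed product differs from recorded product")))
  }
  if (format_sequence(state) != format_sequence(route$end))
    return(list(valid = FALSE, first_failure = list(
      step = nrow(route$steps), message = "route does not end at target")))
  list(valid = TRUE, first_failure = NULL)
}

#' Enumerate all chains reachable from a seed
#'
#' Breadth-first enumeration of every distinct structure reachable
#' within `max_steps` enzyme actions; the backbone of library-coverage
#' questions ("which structures can this enzyme set make?").
#'
#' @param seed starting `hs_oligo`.
#' @param max_steps non-negative step bound.
#' @param control rule options.
#' @return character vector of canonical sequence strings (the seed
#'   included), sorted; deterministic for identical inputs.
#' @examples
#' enumerate_library(get_fixture("seed")$oligo, 3)
#' @export
enumerate_library <- function(seed, max_steps, control = planner_control()) {
  stopifnot(inherits(seed, "hs_oligo"), max_steps >= 0)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  aglycone <- seed$aglycone
  assign(.state_key(seed$tokens), TRUE, envir = seen)
  frontier <- list(seed$tokens)
  if (max_steps > 0) {
    for (depth in seq_len(max_steps)) {
      nxt <- list()
      for (tok in frontier) {
        for (succ in .successors(tok, control)) {
          key <- .state_key(succ$tokens)
          if (is.null(seen[[key]])) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- succ$tokens
          }
        }
      }
      if (length(nxt) == 0L) break
      frontier <- nxt
    }
  }
  keys <- ls(seen, sorted = TRUE)
  vapply(keys, function(k)
    format_sequence(hs_oligo_from_tokens(
      strsplit(k, ".", fixed = TRUE)[[1]], aglycone)), "",
    USE.NAMES = FALSE)
}
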