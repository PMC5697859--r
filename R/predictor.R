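#' Collect candidate-PB profiles for every pentapeptide of a query
#'
#' Slides a 5-residue window along the query sequence and queries the
#' knowledge base for each window: exact 5-mer first, then (only if the exact
#' query is empty) the 4-mer-prefix wildcard. The resulting per-window
#' candidate profiles — the "lists of all possible PBs" with raw S1 counts —
#' are the input of both prediction methods.
#'
#' With `ladder` supplied (a named list of accessible chain sets ordered from
#' closest homologues to most distant, see [tier_ladder()]), each window
#' independently walks the ladder and takes its profile from the first rung
#' with a non-empty exact hit; the wildcard fallback is consulted, again
#' closest-first, only when every rung misses on the exact 5-mer. This is the
#' noise-filtering querying scheme. With `accessible` supplied instead, a
#' single chain set is used (the classic scheme).
#'
#' @param query Amino-acid sequence string (length at least 5).
#' @param db A `pentadb`.
#' @param accessible Chain-id vector for the classic scheme, or `NULL` for no
#'   restriction.
#' @param ladder Named list of chain-id vectors for the noise-filtering
#'   scheme; overrides `accessible`.
#' @return A tibble with one row per window: `position` (window start),
#'   `aa5`, `match_kind`, `tier_used` (rung name or `NA`), and list-column
#'   `profile` (each a tibble `pb`, `count`). Attribute `query_length` holds
#'   the query length.
#' @export
collect_profiles <- function(query, db, accessible = NULL, ladder = NULL) {
  query <- toupper(query)
  L <- nchar(query)
  if (L < 5L) stop("query must have at least 5 residues")
  pos <- seq_len(L - 4L)
  aa5s <- substring(query, pos, pos + 4L)
  one <- function(aa5) {
    if (is.null(ladder)) {
      p <- query_exact(db, aa5, accessible)
      if (match_kind(p) == "none") p <- query_wildcard(db, aa5, accessible)
      return(list(profile = p, tier = NA_character_))
    }
    if (length(ladder) == 0L) stop("empty tier ladder")
    for (nm in names(ladder)) {
      p <- query_exact(db, aa5, ladder[[nm]])
      if (match_kind(p) != "none") return(list(profile = p, tier = nm))
    }
    for (nm in names(ladder)) {
      p <- query_wildcard(db, aa5, ladder[[nm]])
      if (match_kind(p) != "none") return(list(profile = p, tier = nm))
    }
    list(profile = empty_profile(), tier = NA_character_)
  }
  res <- purrr::map(aa5s, one)
  out <- tibble::tibble(
    position = pos,
    aa5 = aa5s,
    match_kind = purrr::map_chr(res, ~ match_kind(.x$profile)),
    tier_used = purrr::map_chr(res, "tier"),
    profile = purrr::map(res, "profile")
  )
  attr(out, "query_length") <- L
  out
}

#' Homologue-tier ladder for the noise-filtering scheme
#'
#' Builds the ordered list of accessible chain sets a query walks under
#' noise filtering. `start = "100"` begins with chains sharing 100% identity
#' with the query (its co-cluster at the 100% threshold) and widens through
#' the 95, 90, 70, 50, 40 and 30% co-clusters down to the whole database.
#' `start = "<t"` first discards every chain sharing at least `t`% identity
#' with the query — the same cut-off as the classic scheme at `<t` — and walks
#' the remaining co-cluster rungs closest-first. `"<30"` therefore collapses
#' to a single rung identical to the classic scheme at the 30% cut-off. The
#' query chain itself is excluded from every rung.
#'
#' @param tiers A tier table.
#' @param query_chain Chain identifier of the query.
#' @param start `"100"` or one of `"<100"`, `"<95"`, `"<90"`, `"<70"`,
#'   `"<50"`, `"<40"`, `"<30"`.
#' @return A named list of chain-id vectors, closest rung first.
#' @export
tier_ladder <- function(tiers, query_chain, start = "100") {
  tiers <- validate_tier_table(tiers)
  all_others <- setdiff(tiers$chain, query_chain)
  th_desc <- rev(tier_thresholds()) # 100, 95, 90, 70, 50, 40, 30
  co <- lapply(th_desc, coclustered_chains, tiers = tiers,
               query_chain = query_chain)
  names(co) <- as.character(th_desc)
  if (identical(start, "100")) {
    rungs <- c(co, list(all = all_others))
    names(rungs) <- c(paste0("co", th_desc), "all")
    return(rungs)
  }
  if (!grepl("^<", start)) stop("start must be \"100\" or \"<t\"")
  t0 <- as.integer(sub("^<", "", start))
  if (!t0 %in% tier_thresholds()) stop("unknown ladder start: ", start)
  excluded <- co[[as.character(t0)]]
  keep <- th_desc[th_desc < t0]
  rungs <- lapply(keep, function(t) setdiff(co[[as.character(t)]], excluded))
  names(rungs) <- vapply(keep, function(t) paste0("co", t), "")
  rungs$all <- setdiff(all_others, excluded)
  rungs
}

#' Majority-rule prediction from candidate profiles
#'
#' Per window, picks the PB with the highest raw count (S1 score). When two
#' or more PBs tie for the maximum, all tied letters are recorded and the
#' alphabetically smallest is emitted in the PB string. Windows with no hits
#' at all yield `Z`.
#'
#' @param profiles Output of [collect_profiles()].
#' @return A `pb_prediction` object; see [predict_pb()].
#' @export
predict_majority <- function(profiles) {
  picks <- purrr::map(profiles$profile, pick_argmax, scores = NULL)
  finish_prediction(profiles, picks, method = "majority")
}

#' Contextual S2 scores for a window's candidate PBs
#'
#' For each candidate central PB `y` of a window, sums the normalized
#' frequencies (odds) of every tri-PB motif `x y z` that can be formed with
#' the candidate PBs `x` of the preceding window and `z` of the succeeding
#' window. A missing or empty neighbour (terminus, no-hit window) contributes
#' the full 16-letter alphabet on that side. Tri-PBs absent from the table
#' contribute zero.
#'
#' @param candidates Character vector of candidate central PBs.
#' @param prev_candidates,next_candidates Candidate sets of the flanking
#'   windows, or `NULL`.
#' @param tripb A tri-PB frequency table ([pb_frequency_table()] with
#'   `order = 3`), or a named numeric vector of motif odds.
#' @return Named numeric vector of S2 scores over `candidates`.
#' @export
s2_scores <- function(candidates, prev_candidates, next_candidates, tripb) {
  odds <- freq_lookup(tripb)
  xs <- if (is.null(prev_candidates) || length(prev_candidates) == 0L) {
    letters[1:16]
  } else prev_candidates
  zs <- if (is.null(next_candidates) || length(next_candidates) == 0L) {
    letters[1:16]
  } else next_candidates
  vapply(candidates, function(y) {
    motifs <- as.vector(outer(xs, zs, function(x, z) paste0(x, y, z)))
    sum(odds[motifs], na.rm = TRUE)
  }, numeric(1))
}

freq_lookup <- function(tripb) {
  if (is.numeric(tripb)) return(tripb)
  stopifnot(inherits(tripb, "pb_freq_table"))
  stats::setNames(tripb$freq, tripb$motif)
}

#' Hybrid (S1 x S2) prediction from candidate profiles
#'
#' Per window, multiplies each candidate's raw count (S1) by its contextual
#' S2 score (see [s2_scores()]) and picks the highest product. Should every
#' product be zero (all tri-PBs formed with the neighbours unobserved), the
#' window falls back to the majority rule rather than dropping to `Z`. Ties
#' are handled as in [predict_majority()].
#'
#' @inheritParams predict_majority
#' @inheritParams s2_scores
#' @return A `pb_prediction` object; see [predict_pb()].
#' @export
predict_hybrid <- function(profiles, tripb) {
  odds <- freq_lookup(tripb)
  cand_sets <- purrr::map(profiles$profile, "pb")
  n <- nrow(profiles)
  picks <- vector("list", n)
  for (w in seq_len(n)) {
    prof <- profiles$profile[[w]]
    if (nrow(prof) == 0L) {
      pick <- pick_argmax(prof, NULL)
      pick$s2_all_zero <- NA
      pick$s2 <- list(numeric())
      picks[[w]] <- pick
      next
    }
    prev <- if (w > 1L) cand_sets[[w - 1L]] else NULL
    nxt <- if (w < n) cand_sets[[w + 1L]] else NULL
    s2 <- s2_scores(prof$pb, prev, nxt, odds)
    score <- prof$count * s2
    if (all(score == 0)) {
      pick <- pick_argmax(prof, NULL) # all context motifs unobserved
      pick$s2_all_zero <- TRUE
    } else {
      pick <- pick_argmax(prof, score)
      pick$s2_all_zero <- FALSE
    }
    pick$s2 <- list(stats::setNames(s2, prof$pb))
    picks[[w]] <- pick
  }
  finish_prediction(profiles, picks, method = "hybrid")
}

# argmax over a profile; scores = NULL means use raw counts (majority rule)
pick_argmax <- function(profile, scores) {
  if (nrow(profile) == 0L) {
    return(list(chosen = "Z", tie = FALSE, tied = list(character())))
  }
  s <- if (is.null(scores)) profile$count else scores
  top <- which(s == max(s))
  tied <- sort(profile$pb[top])
  list(chosen = tied[1L], tie = length(tied) > 1L, tied = list(tied))
}

finish_prediction <- function(profiles, picks, method) {
  L <- attr(profiles, "query_length")
  details <- tibble::tibble(
    position = profiles$position + 2L, # central residue of each window
    aa5 = profiles$aa5,
    match_kind = profiles$match_kind,
    tier_used = profiles$tier_used,
    profile = profiles$profile,
    chosen = purrr::map_chr(picks, "chosen"),
    tie = purrr::map_lgl(picks, "tie"),
    tied = purrr::map(picks, ~ .x$tied[[1]])
  )
  if (!is.null(picks[[1]]$s2)) {
    details$s2 <- purrr::map(picks, ~ .x$s2[[1]])
    details$s2_all_zero <- purrr::map_lgl(picks, "s2_all_zero")
  }
  pb <- rep("Z", L)
  pb[details$position] <- details$chosen
  structure(
    list(pb = paste(pb, collapse = ""), method = method, details = details),
    class = "pb_prediction"
  )
}

#' Predict the PB sequence of an amino-acid query
#'
#' End-to-end prediction: collects per-window candidate profiles from the
#' knowledge base under the requested querying scheme, then applies the
#' majority rule or the hybrid S1 x S2 method. Terminal residues (1, 2, L-1,
#' L) and windows with no hits are `Z`.
#'
#' @param query Amino-acid sequence string (length at least 5).
#' @param db A `pentadb`.
#' @param method `"hybrid"` (default) or `"majority"`.
#' @param scheme `"classic"` (a single identity cut-off) or `"noise-filter"`
#'   (closest-homologue-first ladder).
#' @param threshold Classic scheme cut-off: 30, 40, 50, 70, 90, 95, 100 or
#'   `"full"`.
#' @param start Noise-filter ladder start; see [tier_ladder()].
#' @param query_chain Chain identifier of the query in the tier table; used
#'   for self-exclusion and homologue tiers. `NULL` (classic + `"full"` only)
#'   applies no restriction beyond the database content.
#' @param tripb Tri-PB frequency table; required for the hybrid method.
#' @return A `pb_prediction`: fields `pb` (the predicted string), `method`,
#'   `details` (per-window tibble with profiles, S2 scores, tie flags,
#'   `tier_used`, `match_kind`). [tidy()] returns the per-window table,
#'   [glance()] a one-row summary.
#' @export
predict_pb <- function(query, db, method = c("hybrid", "majority"),
                       scheme = c("classic", "noise-filter"),
                       threshold = "full", start = "100",
                       query_chain = NULL, tripb = NULL) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  if (method == "hybrid" && is.null(tripb)) {
    stop("the hybrid method requires a tri-PB frequency table")
  }
  if (scheme == "noise-filter") {
    if (is.null(query_chain)) stop("noise filtering requires query_chain")
    ladder <- tier_ladder(db$tiers, query_chain, start)
    profiles <- collect_profiles(query, db, ladder = ladder)
  } else {
    acc <- if (is.null(query_chain)) {
      if (!identical(threshold, "full")) {
        stop("classic scheme with a finite threshold requires query_chain")
      }
      NULL
    } else {
      accessible_chains(db$tiers, query_chain, threshold)
    }
    profiles <- collect_profiles(query, db, accessible = acc)
  }
  res <- if (method == "majority") predict_majority(profiles) else {
    predict_hybrid(profiles, tripb)
  }
  res$scheme <- scheme
  res$query <- toupper(query)
  res
}

#' @export
print.pb_prediction <- function(x, ...) {
  cat("PB prediction (", x$method,
      if (!is.null(x$scheme)) paste0(", ", x$scheme), ")\n", sep = "")
  cat("  ", x$pb, "\n", sep = "")
  s <- glance.pb_prediction(x)
  cat("  windows: ", s$n_windows, " (exact ", s$n_exact, ", wildcard ",
      s$n_wildcard, ", none ", s$n_none, ", ties ", s$n_tie, ")\n", sep = "")
  invisible(x)
}

#' Tidy per-window details of a PB prediction
#'
#' @param x A `pb_prediction`.
#' @param ... Unused.
#' @return The per-window tibble (`position` is the central residue).
#' @export
tidy.pb_prediction <- function(x, ...) x$details

#' One-row summary of a PB prediction
#'
#' @inheritParams tidy.pb_prediction
#' @return A tibble with window counts by match kind and tie count.
#' @export
glance.pb_prediction <- function(x, ...) {
  d <- x$details
  tibble::tibble(
    method = x$method,
    scheme = x$scheme %||% NA_character_,
    length = nchar(x$pb),
    n_windows = nrow(d),
    n_exact = sum(d$match_kind == "exact"),
    n_wildcard = sum(d$match_kind == "wildcard"),
    n_none = sum(d$match_kind == "none"),
    n_tie = sum(d$tie)
  )
}
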