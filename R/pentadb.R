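#' Build the pentapeptide knowledge base
#'
#' Slides a 5-residue window along every chain and stores one record per
#' pentapeptide whose central residue has a defined PB: the 5-mer amino-acid
#' string, the central-residue PB, the source chain and the window start
#' position. Together with a tier table (cluster membership of every chain at
#' each sequence-identity threshold) this supports homologue-filtered querying
#' and query self-exclusion. Records are held in a table keyed on the 5-mer
#' and on its 4-mer prefix for exact and wildcard lookup.
#'
#' @param chains A data frame with one row per chain: columns `chain`
#'   (identifier), `aa` (amino-acid sequence, uppercase; nonstandard residues
#'   as `X`) and `pb` (PB sequence of equal length over `a`-`p` and `Z`).
#' @param tiers A tier table as returned by [toy_identity_clusterer()] or
#'   [read_tier_table()]: column `chain` plus `cluster30`, `cluster40`,
#'   `cluster50`, `cluster70`, `cluster90`, `cluster95`, `cluster100`. Every
#'   chain in `chains` must have a row.
#' @return An object of class `pentadb`.
#' @examples
#' chains <- tibble::tibble(chain = "A", aa = "AAAAAA", pb = "ZZmmZZ")
#' db <- build_pentadb(chains, trivial_tier_table("A"))
#' db
#' @export
build_pentadb <- function(chains, tiers) {
  stopifnot(all(c("chain", "aa", "pb") %in% names(chains)))
  tiers <- validate_tier_table(tiers)
  missing <- setdiff(chains$chain, tiers$chain)
  if (length(missing) > 0L) {
    stop("chains absent from tier table: ", paste(missing, collapse = ", "))
  }
  recs <- purrr::pmap(chains[c("chain", "aa", "pb")], function(chain, aa, pb) {
    if (nchar(aa) != nchar(pb)) {
      stop("aa and pb sequences differ in length for chain ", chain)
    }
    L <- nchar(aa)
    if (L < 5L) return(NULL)
    pos <- seq_len(L - 4L)
    central <- substring(pb, pos + 2L, pos + 2L)
    keep <- central != "Z"
    if (!any(keep)) return(NULL)
    tibble::tibble(
      aa5 = toupper(substring(aa, pos[keep], pos[keep] + 4L)),
      pb = central[keep],
      chain = chain,
      position = pos[keep]
    )
  })
  recs <- dplyr::bind_rows(recs)
  new_pentadb(recs, tiers)
}

new_pentadb <- function(records, tiers) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    dt <- data.table::data.table(aa5 = character(), pb = character(),
                                 chain = character(), position = integer())
  }
  dt[, aa4 := substr(aa5, 1L, 4L)]
  data.table::setkey(dt, aa5)
  data.table::setindex(dt, aa4)
  structure(list(records = dt, tiers = tibble::as_tibble(tiers)),
            class = "pentadb")
}

#' @export
print.pentadb <- function(x, ...) {
  s <- pentadb_stats(x)
  cat("Pentapeptide knowledge base\n")
  cat("  records:            ", s$n_records, "\n")
  cat("  unique 5-mers:      ", s$n_unique, "\n")
  cat("  source chains:      ", s$n_chains, "\n")
  invisible(x)
}

#' Summary statistics of a pentapeptide knowledge base
#'
#' Total and unique pentapeptide counts and the number of source chains --
#' the knowledge-base content statistics reported when a database subset is
#' characterised.
#'
#' @param db A `pentadb`.
#' @return A one-row tibble with `n_records`, `n_unique`, `n_chains` and
#'   `n_possible` (the theoretical 20^5 amino-acid pentapeptide space the
#'   unique count is measured against).
#' @export
pentadb_stats <- function(db) {
  stopifnot(inherits(db, "pentadb"))
  tibble::tibble(
    n_records = nrow(db$records),
    n_unique = data.table::uniqueN(db$records$aa5),
    n_chains = data.table::uniqueN(db$records$chain),
    n_possible = 20^5
  )
}

#' Tier thresholds supported by the knowledge base
#' @keywords internal
tier_thresholds <- function() c(30L, 40L, 50L, 70L, 90L, 95L, 100L)

tier_cols <- function() paste0("cluster", tier_thresholds())

validate_tier_table <- function(tiers) {
  tiers <- tibble::as_tibble(tiers)
  need <- c("chain", tier_cols())
  if (!all(need %in% names(tiers))) {
    stop("tier table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tiers$chain)) stop("duplicate chains in tier table")
  tiers
}

#' A tier table placing every chain in its own cluster at all thresholds
#'
#' Convenience for worlds with no homology structure: no two chains are
#' co-clustered at any threshold, so every chain is accessible to every query
#' at every identity cut-off (except the query itself).
#'
#' @param chain_ids Character vector of chain identifiers.
#' @return A tier table tibble.
#' @export
trivial_tier_table <- function(chain_ids) {
  out <- tibble::tibble(chain = chain_ids)
  for (col in tier_cols()) out[[col]] <- chain_ids
  out
}

#' Chains accessible to a query at a sequence-identity cut-off
#'
#' Under the classic querying scheme at cut-off `t`, only pentapeptides from
#' chains sharing *less than* `t`% sequence identity with the query are
#' accessible: operationally, chains not co-clustered with the query chain at
#' the `t`% threshold. `"full"` admits every chain. The query chain itself is
#' always excluded.
#'
#' @param tiers A tier table.
#' @param query_chain Chain identifier of the query.
#' @param threshold One of 30, 40, 50, 70, 90, 95, 100 or `"full"`.
#' @return Character vector of accessible chain identifiers.
#' @export
accessible_chains <- function(tiers, query_chain, threshold = "full") {
  tiers <- validate_tier_table(tiers)
  others <- setdiff(tiers$chain, query_chain)
  if (identical(threshold, "full") || identical(threshold, "FULL")) {
    return(others)
  }
  threshold <- as.integer(threshold)
  if (!threshold %in% tier_thresholds()) {
    stop("unknown identity threshold: ", threshold)
  }
  col <- paste0("cluster", threshold)
  if (!query_chain %in% tiers$chain) return(others)
  qc <- tiers[[col]][tiers$chain == query_chain]
  setdiff(tiers$chain[tiers[[col]] != qc], query_chain)
}

#' Chains co-clustered with a query at a threshold
#'
#' The complement used by the noise-filtering ladder: chains sharing at least
#' `threshold`% identity with the query (same cluster at that threshold),
#' excluding the query itself.
#'
#' @inheritParams accessible_chains
#' @return Character vector of chain identifiers.
#' @export
coclustered_chains <- function(tiers, query_chain, threshold) {
  tiers <- validate_tier_table(tiers)
  threshold <- as.integer(threshold)
  if (!threshold %in% tier_thresholds()) {
    stop("unknown identity threshold: ", threshold)
  }
  col <- paste0("cluster", threshold)
  if (!query_chain %in% tiers$chain) return(character())
  qc <- tiers[[col]][tiers$chain == query_chain]
  setdiff(tiers$chain[tiers[[col]] == qc], query_chain)
}

#' Query the knowledge base for a pentapeptide
#'
#' `query_exact()` counts, over records from accessible chains, the central
#' PBs observed for the exact 5-mer — the "list of all possible PBs" with
#' their raw S1 counts. `query_wildcard()` is the fallback consulted only when
#' the exact query comes back empty: it matches the first four residues with a
#' wildcard at the fifth position.
#'
#' @param db A `pentadb`.
#' @param aa5 A 5-letter uppercase amino-acid string.
#' @param accessible Character vector of accessible source chains (see
#'   [accessible_chains()]), or `NULL` for no restriction.
#' @return A candidate profile: tibble with columns `pb` and `count` (sorted
#'   by letter), with attribute `match_kind` one of `"exact"`, `"wildcard"`,
#'   `"none"`.
#' @export
query_exact <- function(db, aa5, accessible = NULL) {
  stopifnot(inherits(db, "pentadb"), nchar(aa5) == 5L)
  kv <- toupper(aa5)
  hits <- db$records[list(kv), on = "aa5", nomatch = NULL]
  profile_from_hits(hits, accessible, "exact")
}

#' @rdname query_exact
#' @export
query_wildcard <- function(db, aa5, accessible = NULL) {
  stopifnot(inherits(db, "pentadb"), nchar(aa5) == 5L)
  key <- toupper(substr(aa5, 1L, 4L))
  if (grepl("X", key, fixed = TRUE)) {
    # X never matches as a wildcard stand-in for concrete residues
    hits <- db$records[0L]
  } else {
    hits <- db$records[aa4 == key]
  }
  profile_from_hits(hits, accessible, "wildcard")
}

profile_from_hits <- function(hits, accessible, kind) {
  if (!is.null(accessible)) hits <- hits[chain %in% accessible]
  if (nrow(hits) == 0L) {
    return(empty_profile())
  }
  counts <- hits[, .N, by = pb][order(pb)]
  structure(tibble::tibble(pb = counts$pb, count = counts$N),
            match_kind = kind)
}

empty_profile <- function() {
  structure(tibble::tibble(pb = character(), count = integer()),
            match_kind = "none")
}

#' @rdname query_exact
#' @param profile A candidate profile.
#' @export
match_kind <- function(profile) attr(profile, "match_kind") %||% "none"

#' Persist and reload a pentapeptide knowledge base
#'
#' The store is two plain TSV files under `dir`: `records.tsv` (aa5, pb,
#' chain, position) and `tiers.tsv` (the tier table). Reloading rebuilds the
#' lookup keys; record counts are conserved exactly.
#'
#' @param db A `pentadb`.
#' @param dir Directory to write into (created if needed).
#' @return `write_pentadb()`: `dir` invisibly; `read_pentadb()`: a `pentadb`.
#' @export
write_pentadb <- function(db, dir) {
  stopifnot(inherits(db, "pentadb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- tibble::as_tibble(db$records)[c("aa5", "pb", "chain", "position")]
  readr::write_tsv(recs, file.path(dir, "records.tsv"), progress = FALSE)
  readr::write_tsv(db$tiers, file.path(dir, "tiers.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_pentadb
#' @export
read_pentadb <- function(dir) {
  recs <- readr::read_tsv(file.path(dir, "records.tsv"),
                          col_types = "ccci", progress = FALSE)
  tiers <- readr::read_tsv(file.path(dir, "tiers.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  tiers[] <- lapply(tiers, as.character)
  new_pentadb(recs, validate_tier_table(tiers))
}

#' Read or write a tier table TSV
#'
#' @param file Path to a TSV with columns `chain`, `cluster30` ..
#'   `cluster100`.
#' @return A tier table tibble.
#' @export
read_tier_table <- function(file) {
  tiers <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  tiers[] <- lapply(tiers, as.character)
  validate_tier_table(tiers)
}

#' @rdname read_tier_table
#' @param tiers A tier table.
#' @export
write_tier_table <- function(tiers, file) {
  readr::write_tsv(validate_tier_table(tiers), file, progress = FALSE)
  invisible(file)
}

#' Greedy single-linkage identity clustering for small sequence sets
#'
#' A fixture-scale stand-in for large-scale identity clustering: computes
#' global pairwise percent identity (Needleman-Wunsch alignment; identities
#' over alignment length) for every sequence pair, then single-linkage
#' clusters at each threshold. Deterministic given input order. Intended for
#' at most a few hundred sequences.
#'
#' @param seqs Named character vector of amino-acid sequences (names become
#'   chain identifiers).
#' @param thresholds Integer identity thresholds (percent).
#' @return A tier table tibble (cluster labels are the lexicographically
#'   smallest member chain of each cluster).
#' @export
toy_identity_clusterer <- function(seqs, thresholds = tier_thresholds()) {
  if (length(seqs) == 0L) {
    out <- tibble::tibble(chain = character())
    for (t in thresholds) out[[paste0("cluster", t)]] <- character()
    return(out)
  }
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(seqs)
  pid <- diag(100, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pid[i, j] <- pid[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
      }
    }
  }
  out <- tibble::tibble(chain = ids)
  for (t in thresholds) {
    adj <- pid >= t
    labels <- single_linkage_components(adj)
    out[[paste0("cluster", t)]] <- vapply(
      labels, function(l) min(ids[labels == l]), ""
    )
  }
  out
}

# Global percent identity: identities / alignment length ("PID3").
pairwise_identity <- function(s1, s2) {
  if (nchar(s1) == 0L || nchar(s2) == 0L) return(0)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aln <- Biostrings::pairwiseAlignment(
      s1, s2, type = "global",
      substitutionMatrix = NULL, gapOpening = 10, gapExtension = 0.5
    )
    return(Biostrings::pid(aln, type = "PID3"))
  }
  # ungapped fallback for equal-length sequences
  if (nchar(s1) != nchar(s2)) {
    stop("Biostrings is required to align sequences of unequal length")
  }
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  100 * mean(a == b)
}

single_linkage_components <- function(adj) {
  n <- nrow(adj)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(labels[nb], labels[i])
      if (any(labels[c(i, nb)] != m)) {
        labels[c(i, nb)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

`%||%` <- function(x, y) if (is.null(x)) y else x
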