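#' Default PB transition weights from prototype window compatibility
#'
#' Consecutive residues' PB windows overlap in six of their eight dihedral
#' angles, so a letter pair `x -> y` is geometrically plausible only when the
#' trailing six angles of `x`'s prototype agree with the leading six of
#' `y`'s. The default generator graph keeps the transitions whose overlap
#' RMSDA is below `cutoff`, pruned to the strongly connected core (letters
#' from which sampling can continue indefinitely), with weights decaying in
#' the overlap deviation. Strings sampled from this graph are exactly
#' recoverable by [encode_chain()] after [build_backbone()]: every admissible
#' five-letter context re-assigns its central letter, with a comfortable
#' RMSDA margin to the runner-up prototype.
#'
#' Zero-weight rows (letters excluded from the core: the transition blocks
#' whose own window overlaps are internally inconsistent under central-angle
#' reconstruction) are never visited when sampling starts inside the core.
#'
#' @param cutoff Maximum overlap RMSDA (degrees) for an admissible
#'   transition.
#' @param scale Exponential decay scale (degrees) of the weights.
#' @inheritParams pb_prototype_matrix
#' @return A 16 x 16 non-negative matrix, rows = current letter, columns =
#'   next letter.
#' @export
pb_transition_weights <- function(cutoff = 40, scale = 20,
                                  alphabet = pb_alphabet()) {
  proto <- pb_prototype_matrix(alphabet)
  d_ov <- matrix(0, 16L, 16L,
                 dimnames = list(rownames(proto), rownames(proto)))
  for (x in 1:16) {
    for (y in 1:16) {
      d_ov[x, y] <- rmsda8_partial(proto[x, 3:8], proto[y, 1:6])
    }
  }
  adj <- d_ov < cutoff
  active <- rep(TRUE, 16L)
  repeat {
    sub <- adj & outer(active, active)
    bad <- active & (rowSums(sub) == 0L | colSums(sub) == 0L)
    if (!any(bad)) break
    active[bad] <- FALSE
  }
  w <- exp(-d_ov / scale) * (adj & outer(active, active))
  w
}

rmsda8_partial <- function(a, b) sqrt(mean(angular_difference(a, b)^2))

#' Sample a PB string from a first-order Markov chain
#'
#' @param length Number of letters to emit.
#' @param weights 16 x 16 non-negative transition matrix with PB letters as
#'   dimnames (rows = current letter); defaults to
#'   [pb_transition_weights()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param start Starting letter; default samples it from the letters with
#'   positive out-weight.
#' @return A PB string of the requested length. Transitions with zero weight
#'   are never emitted; reaching a letter whose row is all zero is an error.
#' @export
sample_pb_string <- function(length, weights = pb_transition_weights(),
                             seed = NULL, start = NULL) {
  stopifnot(is.matrix(weights), all(dim(weights) == 16L),
            all(weights >= 0), length >= 1L)
  lets <- rownames(weights) %||% letters[1:16]
  with_seed_if(seed, {
    if (is.null(start)) {
      viable <- lets[rowSums(weights) > 0]
      if (length(viable) == 0L) stop("all transition rows are zero")
      start <- sample(viable, 1L)
    }
    out <- character(length)
    out[1L] <- start
    for (i in seq_len(length - 1L)) {
      row <- weights[out[i], ]
      if (sum(row) <= 0) {
        stop("all-zero transition row for letter '", out[i], "'")
      }
      out[i + 1L] <- sample(lets, 1L, prob = row)
    }
    paste(out, collapse = "")
  })
}

#' Random amino-acid sequence
#'
#' @param length Number of residues.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param alphabet Residue letters to draw from, as a single string. The
#'   default is the 20 standard amino acids; fixtures use a reduced alphabet
#'   so that 5-mer lookups saturate at desk scale (see [make_fixture()]).
#' @return An uppercase amino-acid string.
#' @export
random_aa_sequence <- function(length, seed = NULL,
                               alphabet = "ACDEFGHIKLMNPQRSTVWY") {
  aa <- strsplit(alphabet, "")[[1]]
  with_seed_if(seed, paste(sample(aa, length, replace = TRUE), collapse = ""))
}

#' Mutate a sequence to a target percent identity
#'
#' Substitutes `round(L * (1 - identity/100))` positions (chosen uniformly,
#' deterministically per seed) with a different residue, so the realized
#' ungapped identity to the input equals the target within one position.
#'
#' @param aa_seq Amino-acid sequence string.
#' @param target_identity Percent identity in `(0, 100]`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @inheritParams random_aa_sequence
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(aa_seq, target_identity, seed = NULL,
                            alphabet = "ACDEFGHIKLMNPQRSTVWY") {
  stopifnot(target_identity > 0, target_identity <= 100)
  L <- nchar(aa_seq)
  n_sub <- round(L * (1 - target_identity / 100))
  if (n_sub == 0L) return(aa_seq)
  aa <- strsplit(alphabet, "")[[1]]
  with_seed_if(seed, {
    s <- strsplit(aa_seq, "")[[1]]
    pos <- sample(L, n_sub)
    for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1L)
    paste(s, collapse = "")
  })
}

#' Generate a self-contained test world
#'
#' Builds `n_families` unrelated protein families. Each family has a master
#' PB string (sampled from the compatibility-restricted Markov chain), one
#' backbone realizing it (central prototype angles plus Gaussian dihedral
#' noise), and `chains_per_family` member chains that share the master's
#' coordinates and PB truth but carry amino-acid sequences mutated to the
#' identities in `identity_schedule` (recycled; the first entry is
#' conventionally 100, the unmutated master). The tier table is derived from
#' the schedule itself: a member chain is co-clustered with its family at
#' every threshold at or below its identity to the master (single linkage
#' through the master); unrelated families are never co-clustered. Measuring
#' identities instead with [toy_identity_clusterer()] recovers the same
#' within-family structure; the schedule form keeps the tiers exact at
#' threshold boundaries.
#'
#' Sequences are drawn from a reduced amino-acid alphabet (default 4
#' letters). With the full 20-letter alphabet a desk-scale database would
#' contain essentially no cross-family 5-mer collisions, so queries without
#' accessible homologues would return nothing at all; a real structure
#' database, being many orders of magnitude larger, observes most
#' pentapeptides even among unrelated proteins. The reduced alphabet restores
#' that saturation regime (a few thousand possible 5-mers against a few
#' hundred observed windows).
#'
#' Sharing coordinates across a family isolates the sequence-lookup machinery
#' from structural divergence: a 100%-identity homologue in the knowledge
#' base really does carry the query's correct PBs. Real homologous
#' structures diverge; the vignette discusses what this idealization does and
#' does not test.
#'
#' @param n_families Number of unrelated families.
#' @param chains_per_family Chains per family.
#' @param chain_length Residues per chain (at least 5).
#' @param identity_schedule Percent identities of member chains to their
#'   family master.
#' @param noise_sigma Dihedral noise (degrees) applied when building each
#'   family backbone.
#' @param aa_alphabet Residue letters fixture sequences are drawn from.
#' @param seed Integer seed; the whole world is deterministic given it.
#' @param dir Optional directory: when given, writes one PDB per chain plus
#'   `aa.fasta`, `pb.fasta` (alphabet `a`-`p` + `Z`) and `tiers.tsv`.
#' @return A list of class `pb_fixture`: `chains` (tibble with `chain`,
#'   `family`, `identity`, `aa`, `pb`), `backbones` (named list of backbone
#'   tibbles, one per chain), `tiers` (tier table), `seed`.
#' @export
make_fixture <- function(n_families = 3L, chains_per_family = 4L,
                         chain_length = 40L,
                         identity_schedule = c(100, 95, 70, 40),
                         noise_sigma = 2, aa_alphabet = "ACDE",
                         seed = 1L, dir = NULL) {
  stopifnot(chain_length >= 5L, n_families >= 1L, chains_per_family >= 1L)
  ids <- rep_len(identity_schedule, chains_per_family)
  weights <- pb_transition_weights()
  rows <- list()
  backbones <- list()
  for (f in seq_len(n_families)) {
    fseed <- seed * 1000L + f
    pb_master <- sample_pb_string(chain_length, weights, seed = fseed)
    aa_master <- random_aa_sequence(chain_length, seed = fseed + 500L,
                                    alphabet = aa_alphabet)
    bb <- build_backbone(pb_master, noise_sigma = noise_sigma,
                         seed = fseed + 250L)
    pb_truth <- encode_chain(phi_psi_series(bb))
    for (j in seq_len(chains_per_family)) {
      id <- sprintf("F%dC%d", f, j)
      aa_j <- mutate_sequence(aa_master, ids[j], seed = fseed + 10L * j,
                              alphabet = aa_alphabet)
      bb_j <- bb
      bb_j$chain <- id
      bb_j$aa <- pb_letters(aa_j)
      bb_j$resname <- aa_123(bb_j$aa)
      rows[[id]] <- tibble::tibble(
        chain = id, family = f, identity = ids[j], aa = aa_j, pb = pb_truth
      )
      backbones[[id]] <- bb_j
    }
  }
  chains <- dplyr::bind_rows(rows)
  tiers <- schedule_tier_table(chains)
  out <- structure(
    list(chains = chains, backbones = backbones, tiers = tiers, seed = seed),
    class = "pb_fixture"
  )
  if (!is.null(dir)) write_fixture(out, dir)
  out
}

#' Tier table implied by a fixture's identity schedule
#'
#' A member chain is co-clustered with the rest of its family at every
#' threshold not exceeding its identity to the family master; single linkage
#' through the master then merges members within a family. Chains from
#' different families never share a cluster.
#'
#' @param chains A fixture chain tibble (`chain`, `family`, `identity`).
#' @return A tier table tibble.
#' @export
schedule_tier_table <- function(chains) {
  stopifnot(all(c("chain", "family", "identity") %in% names(chains)))
  out <- tibble::tibble(chain = chains$chain)
  for (t in tier_thresholds()) {
    lab <- chains$chain # default: own singleton cluster
    for (f in unique(chains$family)) {
      idx <- which(chains$family == f & chains$identity >= t)
      if (length(idx) > 1L) lab[idx] <- min(chains$chain[idx])
    }
    out[[paste0("cluster", t)]] <- lab
  }
  out
}

#' @export
print.pb_fixture <- function(x, ...) {
  cat("Synthetic PB fixture:", nrow(x$chains), "chains in",
      length(unique(x$chains$family)), "families\n")
  invisible(x)
}

#' @rdname make_fixture
#' @param fixture A `pb_fixture`.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "pb_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(fixture$backbones)) {
    write_backbone_pdb(fixture$backbones[[id]],
                       file.path(dir, paste0(id, ".pdb")))
  }
  write_fasta(stats::setNames(fixture$chains$aa, fixture$chains$chain),
              file.path(dir, "aa.fasta"))
  pb <- stats::setNames(fixture$chains$pb, fixture$chains$chain)
  names(pb) <- paste0(names(pb), " alphabet=PB")
  write_fasta(pb, file.path(dir, "pb.fasta"))
  write_tier_table(fixture$tiers, file.path(dir, "tiers.tsv"))
  invisible(dir)
}

#' Knowledge base from a fixture, optionally holding chains out
#'
#' @param fixture A `pb_fixture`.
#' @param exclude Chain identifiers to leave out of the knowledge base (they
#'   stay in the tier table, so they can still be used as queries).
#' @return A `pentadb`.
#' @export
fixture_pentadb <- function(fixture, exclude = character()) {
  stopifnot(inherits(fixture, "pb_fixture"))
  keep <- !fixture$chains$chain %in% exclude
  build_pentadb(fixture$chains[keep, ], fixture$tiers)
}
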