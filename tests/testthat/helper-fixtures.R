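# Shared fixture worlds, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# default world: 3 families x (100, 95, 70, 40)% members
std_fixture <- function() {
  if (is.null(.fixture_cache$std)) .fixture_cache$std <- make_fixture(seed = 101)
  .fixture_cache$std
}

# world whose families contain an identical-sequence homologue pair
dup_fixture <- function() {
  if (is.null(.fixture_cache$dup)) {
    .fixture_cache$dup <- make_fixture(
      identity_schedule = c(100, 100, 70, 40), seed = 202
    )
  }
  .fixture_cache$dup
}

# hand-made candidate-profile table in the collect_profiles() shape
make_profiles <- function(count_maps, query_length = length(count_maps) + 4L) {
  profs <- lapply(count_maps, function(m) {
    if (length(m) == 0L) {
      return(structure(tibble::tibble(pb = character(), count = integer()),
                       match_kind = "none"))
    }
    structure(
      tibble::tibble(pb = names(m)[order(names(m))],
                     count = as.integer(m[order(names(m))])),
      match_kind = "exact"
    )
  })
  out <- tibble::tibble(
    position = seq_along(profs),
    aa5 = strrep("A", 5L),
    match_kind = vapply(profs, function(p) attr(p, "match_kind"), ""),
    tier_used = NA_character_,
    profile = profs
  )
  attr(out, "query_length") <- query_length
  out
}

# a tri-PB odds lookup with every motif over the given letters present
uniform_tripb <- function(value = 1, lets = letters[1:16]) {
  motifs <- as.vector(outer(outer(lets, lets, paste0), lets, paste0))
  stats::setNames(rep(value, length(motifs)), motifs)
}

# independent MCC reference: Pearson correlation of one-vs-rest indicators
mcc_by_cor <- function(cm, pb_index) {
  truth <- rep(rep(seq_len(16), times = 16), times = as.vector(cm))
  pred <- rep(rep(seq_len(16), each = 16), times = as.vector(cm))
  t_ind <- as.numeric(truth == pb_index)
  p_ind <- as.numeric(pred == pb_index)
  if (stats::sd(t_ind) == 0 || stats::sd(p_ind) == 0) return(NA_real_)
  stats::cor(t_ind, p_ind)
}
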