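#' Build a tri-PB or penta-PB motif frequency table
#'
#' Counts every run of `order` consecutive PBs (windows containing `Z` are
#' skipped) across a corpus of PB sequences and normalizes:
#'
#' * `mode = "freq"` — plain frequencies, `count(m) / total`; entries sum
#'   to 1.
#' * `mode = "odds"` — observed motif frequency divided by the product of the
#'   single-PB marginal frequencies of its letters; values above 1 mark
#'   motifs over-represented relative to an independence model.
#'
#' Motifs never observed are absent from the table (implicit zero). Only a
#' small fraction of the motif space is ever realized in native structures
#' (most tri-PB and nearly all penta-PB combinations are stereochemically
#' unfavourable), which is what makes these tables informative.
#'
#' @param pb_seqs Character vector of PB sequences (over `a`-`p` and `Z`).
#' @param order Motif length: 3 (tri-PB, used by the hybrid method's S2
#'   score) or 5 (penta-PB, used by the accuracy score).
#' @param mode `"odds"` or `"freq"`.
#' @return A `pb_freq_table`: tibble with columns `motif`, `count`, `freq`,
#'   and attributes `order`, `mode`, `total_motifs` (windows counted).
#' @export
pb_frequency_table <- function(pb_seqs, order = 3L, mode = c("odds", "freq")) {
  mode <- match.arg(mode)
  if (!order %in% c(3L, 5L)) stop("order must be 3 or 5")
  if (length(pb_seqs) == 0L) stop("empty PB corpus")
  motifs <- unlist(lapply(pb_seqs, function(s) {
    L <- nchar(s)
    if (L < order) return(character())
    starts <- seq_len(L - order + 1L)
    substring(s, starts, starts + order - 1L)
  }))
  motifs <- motifs[!grepl("Z", motifs, fixed = TRUE)]
  if (length(motifs) == 0L) stop("no scorable motif windows in corpus")
  counts <- table(motifs)
  freq <- as.numeric(counts) / sum(counts)
  if (mode == "odds") {
    lets <- unlist(strsplit(motifs, ""))
    marg <- table(factor(lets, levels = letters[1:16]))
    marg <- as.numeric(marg) / sum(marg)
    names(marg) <- letters[1:16]
    denom <- vapply(names(counts), function(m) {
      prod(marg[strsplit(m, "")[[1]]])
    }, numeric(1))
    freq <- (as.numeric(counts) / sum(counts)) / unname(denom)
  }
  structure(
    tibble::tibble(motif = names(counts), count = as.integer(counts),
                   freq = unname(freq)),
    order = order, mode = mode, total_motifs = sum(counts),
    class = c("pb_freq_table", class(tibble::tibble()))
  )
}

#' Motif-space coverage of a frequency table
#'
#' How many distinct motifs were observed, against the theoretically possible
#' `16^order` (4,096 tri-PBs; 1,048,576 penta-PBs).
#'
#' @param table A `pb_freq_table`.
#' @return A one-row tibble: `order`, `observed`, `possible`, `fraction`.
#' @export
motif_coverage <- function(table) {
  stopifnot(inherits(table, "pb_freq_table"))
  order <- attr(table, "order")
  possible <- 16^order
  tibble::tibble(
    order = order,
    observed = nrow(table),
    possible = possible,
    fraction = nrow(table) / possible
  )
}

#' Serialize a frequency table to TSV
#'
#' The header line records the motif order, normalization mode and corpus
#' size as comments so a reloaded table is equivalent to the original.
#'
#' @param table A `pb_freq_table`.
#' @param file Output path.
#' @export
write_freq_table <- function(table, file) {
  stopifnot(inherits(table, "pb_freq_table"))
  hdr <- sprintf("# order=%d mode=%s total_motifs=%d",
                 attr(table, "order"), attr(table, "mode"),
                 attr(table, "total_motifs"))
  writeLines(hdr, file)
  readr::write_tsv(tibble::as_tibble(table), file, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(file)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(file) {
  hdr <- readLines(file, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  tbl <- readr::read_tsv(file, skip = 1L, col_types = "cid", progress = FALSE)
  structure(
    tibble::as_tibble(tbl),
    order = as.integer(vals[["order"]]), mode = vals[["mode"]],
    total_motifs = as.integer(vals[["total_motifs"]]),
    class = c("pb_freq_table", class(tibble::tibble()))
  )
}

#' Accuracy score of a PB sequence
#'
#' Self-estimate of prediction quality from penta-PB plausibility: with a
#' sliding window of five consecutive PBs along the sequence,
#' \deqn{A = \frac{\sum_{i=1}^{l-4} \log N_i}{l}}
#' where \eqn{N_i} is the normalized frequency of the penta-PB motif at
#' window \eqn{i} and \eqn{l} the PB sequence length. A window whose motif
#' was never observed in the reference corpus contributes a flat penalty
#' (default -5) to the sum instead of its log frequency. Leading and trailing
#' `Z` runs are trimmed before scoring; interior windows containing `Z` are
#' skipped and reported separately.
#'
#' Higher scores mark PB sequences whose local motif composition resembles
#' native structures; the score correlates with prediction accuracy, so it
#' serves as an a-posteriori quality estimate when no structure is available.
#'
#' @param pb_seq A PB sequence string.
#' @param penta_table A `pb_freq_table` of order 5.
#' @param penalty Score contribution of an unobserved penta-PB motif.
#' @param log_base Base of the logarithm (default 10).
#' @return A one-row tibble: `score`, `length` (scored length `l`),
#'   `n_windows` (`l - 4`), `n_scored`, `n_penalized`, `n_skipped` (interior
#'   `Z` windows).
#' @export
accuracy_score <- function(pb_seq, penta_table, penalty = -5, log_base = 10) {
  stopifnot(inherits(penta_table, "pb_freq_table"),
            attr(penta_table, "order") == 5L)
  trimmed <- gsub("^Z+|Z+$", "", pb_seq)
  l <- nchar(trimmed)
  if (l < 5L) stop("fewer than one scorable window after trimming Z termini")
  starts <- seq_len(l - 4L)
  motifs <- substring(trimmed, starts, starts + 4L)
  has_z <- grepl("Z", motifs, fixed = TRUE)
  if (all(has_z)) stop("no scorable window: every penta-PB window contains Z")
  odds <- stats::setNames(penta_table$freq, penta_table$motif)
  n <- odds[motifs[!has_z]]
  contrib <- ifelse(is.na(n), penalty, log(n, base = log_base))
  tibble::tibble(
    score = sum(contrib) / l,
    length = l,
    n_windows = l - 4L,
    n_scored = sum(!is.na(n)),
    n_penalized = sum(is.na(n)),
    n_skipped = sum(has_z)
  )
}
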