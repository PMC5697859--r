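#' The Protein Blocks structural alphabet
#'
#' The 16 Protein Blocks (PBs) are canonical five-residue backbone
#' conformations, labelled `a` to `p`, each defined by eight standard dihedral
#' angles covering the pentapeptide window centred on residue *i*:
#' \eqn{(\psi_{i-2}, \phi_{i-1}, \psi_{i-1}, \phi_i, \psi_i, \phi_{i+1},
#' \psi_{i+1}, \phi_{i+2})}. PBs `m` and `d` correspond roughly to the cores of
#' the alpha-helix and the beta-strand. The prototype table shipped with the
#' package is the canonical one of de Brevern, Etchebest & Hazout (2000,
#' *Proteins* 41:271-288); it is read from a TSV so an alternative table can be
#' swapped in.
#'
#' @param file Path to a prototype TSV (`pb` column plus eight angle columns in
#'   window order, degrees). Defaults to the packaged canonical table.
#' @return A tibble with 16 rows and columns `pb`, `psi_m2`, `phi_m1`,
#'   `psi_m1`, `phi`, `psi`, `phi_p1`, `psi_p1`, `phi_p2`.
#' @examples
#' pb_alphabet()
#' @export
pb_alphabet <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.pb_cache$alphabet)) return(.pb_cache$alphabet)
    file <- system.file("extdata", "pb_prototypes.tsv", package = "protblocks",
                        mustWork = TRUE)
    default <- TRUE
  } else {
    default <- FALSE
  }
  tbl <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  stopifnot(
    identical(names(tbl)[1], "pb"), ncol(tbl) == 9L,
    nrow(tbl) == 16L, identical(sort(tbl$pb), letters[1:16])
  )
  ang <- as.matrix(tbl[-1])
  if (any(!is.finite(ang)) || any(ang <= -180 | ang > 180)) {
    stop("prototype angles must be finite and in (-180, 180]")
  }
  if (default) .pb_cache$alphabet <- tbl
  tbl
}

.pb_cache <- new.env(parent = emptyenv())

#' @rdname pb_alphabet
#' @param alphabet An alphabet tibble as returned by [pb_alphabet()].
#' @return For `pb_prototype_matrix()`, a 16 x 8 numeric matrix with the PB
#'   letters as row names, angles in window order.
#' @export
pb_prototype_matrix <- function(alphabet = pb_alphabet()) {
  m <- as.matrix(alphabet[-1])
  rownames(m) <- alphabet$pb
  m[order(rownames(m)), , drop = FALSE]
}

#' Wrapped difference between two angles
#'
#' Returns the signed minimal circular separation `a - b`, wrapped into
#' `(-180, 180]`. Vectorised over both arguments.
#'
#' @param a,b Angles in degrees.
#' @return Degrees in `(-180, 180]`.
#' @examples
#' angular_difference(179, -179) # -2, not 358
#' @export
angular_difference <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("angular_difference() requires finite inputs")
  }
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Root mean square deviation on angular values (RMSDA)
#'
#' The dissimilarity used to assign PBs: the Euclidean distance between two
#' eight-angle dihedral vectors under wrapped angular differences,
#' \eqn{\sqrt{\frac{1}{8}\sum_k \Delta(v_{1k}, v_{2k})^2}}.
#'
#' @param v1,v2 Numeric vectors of 8 dihedral angles (degrees, window order).
#'   Both must be fully defined: incomplete windows cannot be assigned a PB.
#' @return A non-negative scalar in degrees.
#' @export
rmsda <- function(v1, v2) {
  if (length(v1) != 8L || length(v2) != 8L) stop("dihedral vectors have length 8")
  if (any(!is.finite(v1)) || any(!is.finite(v2))) {
    stop("rmsda() requires fully defined dihedral vectors")
  }
  sqrt(mean(angular_difference(v1, v2)^2))
}

#' Assign the Protein Block of a dihedral window
#'
#' Nearest-prototype classification: the PB whose standard dihedral vector has
#' the lowest RMSDA to the observed window is assigned to the central residue.
#' Exact ties (measure-zero in practice) are broken towards the alphabetically
#' smallest letter so assignment is deterministic.
#'
#' @param v Numeric vector of 8 dihedral angles (degrees, window order), fully
#'   defined.
#' @inheritParams pb_prototype_matrix
#' @return A single PB letter in `a`-`p`.
#' @export
assign_pb <- function(v, alphabet = pb_alphabet()) {
  proto <- pb_prototype_matrix(alphabet)
  d <- apply(proto, 1L, rmsda, v2 = normalize_angle(v))
  names(d)[which.min(d)] # which.min takes the first minimum; rows sorted a..p
}

normalize_angle <- function(a) {
  d <- a %% 360
  ifelse(d > 180, d - 360, d)
}

#' Encode a chain of phi/psi angles as a PB sequence
#'
#' Builds, for each residue `i` with `3 <= i <= L - 2`, the eight-angle window
#' \eqn{(\psi_{i-2}, \ldots, \phi_{i+2})} and assigns the nearest PB prototype.
#' The first two and last two residues, and any residue whose window contains
#' an undefined angle (terminus, missing atom, chain break), get the
#' no-assignment letter `Z`. `Z` positions are excluded from every accuracy
#' denominator downstream.
#'
#' @param angles A data frame with numeric columns `phi` and `psi`, one row per
#'   residue in chain order; `NA` marks undefined angles. Typically the output
#'   of [phi_psi_series()].
#' @inheritParams pb_prototype_matrix
#' @return A single PB sequence string over `a`-`p` and `Z`, of length
#'   `nrow(angles)`.
#' @examples
#' helix <- data.frame(phi = rep(-65.54, 8), psi = rep(-38.88, 8))
#' encode_chain(helix)
#' @export
encode_chain <- function(angles, alphabet = pb_alphabet()) {
  stopifnot(is.data.frame(angles), all(c("phi", "psi") %in% names(angles)))
  n <- nrow(angles)
  if (n < 5L) {
    warning("chain shorter than 5 residues: no PB can be assigned")
    return(paste(rep("Z", n), collapse = ""))
  }
  proto <- pb_prototype_matrix(alphabet)
  phi <- normalize_angle(as.numeric(angles$phi))
  psi <- normalize_angle(as.numeric(angles$psi))
  out <- rep("Z", n)
  for (i in 3:(n - 2L)) {
    w <- c(psi[i - 2L], phi[i - 1L], psi[i - 1L], phi[i],
           psi[i], phi[i + 1L], psi[i + 1L], phi[i + 2L])
    if (any(!is.finite(w))) next
    d <- sqrt(rowMeans(angular_difference(
      matrix(w, nrow = 16L, ncol = 8L, byrow = TRUE), proto)^2))
    out[i] <- rownames(proto)[which.min(d)]
  }
  paste(out, collapse = "")
}

#' Split a PB sequence string into letters
#'
#' @param pb_seq A PB sequence string over `a`-`p` and `Z`.
#' @return A character vector of single letters.
#' @keywords internal
pb_letters <- function(pb_seq) {
  stopifnot(is.character(pb_seq), length(pb_seq) == 1L)
  strsplit(pb_seq, "", fixed = TRUE)[[1]]
}
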