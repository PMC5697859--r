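#' Read backbone chains from a PDB file
#'
#' Parses a PDB file (via [bio3d::read.pdb()]) and returns one row per residue
#' with its N/CA/C backbone coordinates. Only the first model of multi-model
#' (e.g. NMR) files is used; where alternate locations exist, the
#' highest-occupancy altloc is kept, ties resolved towards `'A'`. HETATM-only
#' chains are skipped. Residues missing any of N/CA/C are retained but flagged
#' incomplete so dihedrals that depend on them come out undefined.
#'
#' @param file Path to a PDB-format file.
#' @return A tibble with columns `chain`, `resno`, `resname`, `aa` (one-letter,
#'   `X` for nonstandard residues) and the nine coordinate columns
#'   `n_x`..`c_z` (angstroms, `NA` where the atom is absent), plus a logical
#'   `complete`.
#' @export
read_backbone <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  atoms <- tibble::as_tibble(pdb$atom)
  atoms <- dplyr::filter(atoms, .data$type == "ATOM",
                         .data$elety %in% c("N", "CA", "C"))
  if (nrow(atoms) == 0L) {
    warning("no protein ATOM records found")
    return(empty_backbone())
  }
  atoms$o[is.na(atoms$o)] <- 1
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  wide <- atoms |>
    dplyr::mutate(elety = tolower(.data$elety)) |>
    tidyr::pivot_wider(
      id_cols = c("chain", "resno", "insert", "resid"),
      names_from = "elety", values_from = c("x", "y", "z"),
      names_glue = "{elety}_{.value}"
    ) |>
    dplyr::arrange(.data$chain, .data$resno)
  for (col in backbone_coord_cols()) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  tibble::tibble(
    chain = wide$chain,
    resno = wide$resno,
    resname = wide$resid,
    aa = suppressWarnings(bio3d::aa321(wide$resid)),
    wide[backbone_coord_cols()],
    complete = !Reduce(`|`, lapply(wide[backbone_coord_cols()], is.na))
  ) |>
    dplyr::mutate(aa = dplyr::if_else(is.na(.data$aa), "X", .data$aa))
}

backbone_coord_cols <- function() {
  paste(rep(c("n", "ca", "c"), each = 3), c("x", "y", "z"), sep = "_")
}

empty_backbone <- function() {
  out <- tibble::tibble(
    chain = character(), resno = integer(), resname = character(),
    aa = character()
  )
  for (col in backbone_coord_cols()) out[[col]] <- numeric()
  out$complete <- logical()
  out
}

#' Signed torsion angle of four points
#'
#' Standard IUPAC torsion: looking down the `p2`-`p3` bond, the angle is
#' positive for a clockwise rotation of `p3`-`p4` relative to `p1`-`p2`.
#' Trans is 180, cis is 0.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (angstroms).
#' @return Torsion in degrees in `(-180, 180]`, or `NA` for degenerate
#'   geometry (coincident consecutive points or collinear triples).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-9 || sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  ang <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Per-residue phi/psi series of a backbone chain
#'
#' \eqn{\phi_i} is the torsion C(i-1)-N(i)-CA(i)-C(i) and \eqn{\psi_i} the
#' torsion N(i)-CA(i)-C(i)-N(i+1). Angles are undefined (`NA`) at the chain
#' termini, wherever a contributing atom is missing, and across chain breaks
#' (peptide-bond C-N distance above 2.5 angstroms).
#'
#' @param chain A single-chain backbone tibble as returned by
#'   [read_backbone()] or [build_backbone()].
#' @param break_distance Maximum C(i-1)-N(i) distance (angstroms) for the two
#'   residues to count as bonded.
#' @return A tibble with columns `resno`, `aa`, `phi`, `psi`.
#' @export
phi_psi_series <- function(chain, break_distance = 2.5) {
  stopifnot(is.data.frame(chain), length(unique(chain$chain)) <= 1L)
  n <- nrow(chain)
  getp <- function(i, atom) {
    as.numeric(chain[i, paste(atom, c("x", "y", "z"), sep = "_")])
  }
  bonded <- rep(FALSE, n) # bonded[i]: residue i-1 C linked to residue i N
  if (n >= 2L) {
    for (i in 2:n) {
      ci <- getp(i - 1L, "c")
      ni <- getp(i, "n")
      if (any(is.na(ci)) || any(is.na(ni))) next
      bonded[i] <- sqrt(sum((ni - ci)^2)) <= break_distance
    }
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && bonded[i]) {
      phi[i] <- dihedral_angle(getp(i - 1L, "c"), getp(i, "n"),
                               getp(i, "ca"), getp(i, "c"))
    }
    if (i < n && bonded[i + 1L]) {
      psi[i] <- dihedral_angle(getp(i, "n"), getp(i, "ca"),
                               getp(i, "c"), getp(i + 1L, "n"))
    }
  }
  tibble::tibble(resno = chain$resno, aa = chain$aa, phi = phi, psi = psi)
}

# Ideal backbone internal coordinates (angstroms / degrees): Engh-Huber-like
# standard values; omega fixed trans.
.bb_geom <- list(
  len_n_ca = 1.458, len_ca_c = 1.525, len_c_n = 1.329,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  omega = 180
)

#' Build a backbone realizing a PB string
#'
#' Reconstructs N/CA/C coordinates for a chain whose residue `i` adopts the
#' central \eqn{(\phi, \psi)} pair of the prototype of `pb_string[i]`,
#' optionally perturbed by Gaussian angular noise. Placement is sequential
#' (natural-extension internal coordinates) with ideal bond lengths and
#' angles and a fixed trans peptide bond. The construction is the inverse of
#' [encode_chain()] up to the two undefined residues at each terminus:
#' re-encoding the built chain recovers the generating letters at interior
#' positions for compatible PB strings (see [pb_transition_weights()]).
#'
#' @param pb_string A string over `a`-`p`, length at least 5.
#' @param noise_sigma Standard deviation (degrees) of i.i.d. Gaussian noise
#'   added to every phi/psi before placement.
#' @param seed Integer seed making the noise reproducible; `NULL` uses the
#'   current RNG state.
#' @param aa_seq Optional amino-acid sequence (same length) used for residue
#'   names; defaults to poly-alanine.
#' @param chain_id Chain identifier stored in the output.
#' @inheritParams pb_prototype_matrix
#' @return A backbone tibble in the same shape as [read_backbone()] output.
#' @export
build_backbone <- function(pb_string, noise_sigma = 0, seed = NULL,
                           aa_seq = NULL, chain_id = "A",
                           alphabet = pb_alphabet()) {
  pbs <- pb_letters(pb_string)
  if (length(pbs) < 5L) stop("pb_string must have length >= 5")
  if (!all(pbs %in% letters[1:16])) {
    stop("pb_string letters must be in a-p")
  }
  proto <- pb_prototype_matrix(alphabet)
  n <- length(pbs)
  phi <- proto[pbs, "phi"]
  psi <- proto[pbs, "psi"]
  if (noise_sigma > 0) {
    noise <- with_seed_if(seed, stats::rnorm(2L * n, 0, noise_sigma))
    phi <- normalize_angle(phi + noise[seq_len(n)])
    psi <- normalize_angle(psi + noise[n + seq_len(n)])
  }
  g <- .bb_geom
  coords <- matrix(NA_real_, nrow = 3L * n, ncol = 3L) # N, CA, C per residue
  coords[1L, ] <- c(0, 0, 0)
  coords[2L, ] <- c(g$len_n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  coords[3L, ] <- coords[2L, ] + g$len_ca_c * c(cos(th), sin(th), 0)
  for (i in 2:n) {
    r <- 3L * (i - 1L)
    # N(i): torsion psi(i-1) about CA(i-1)-C(i-1)
    coords[r + 1L, ] <- place_atom(coords[r - 2L, ], coords[r - 1L, ],
                                   coords[r, ], g$len_c_n, g$ang_ca_c_n,
                                   psi[i - 1L])
    # CA(i): omega about C(i-1)-N(i)
    coords[r + 2L, ] <- place_atom(coords[r - 1L, ], coords[r, ],
                                   coords[r + 1L, ], g$len_n_ca, g$ang_c_n_ca,
                                   g$omega)
    # C(i): phi(i) about N(i)-CA(i)
    coords[r + 3L, ] <- place_atom(coords[r, ], coords[r + 1L, ],
                                   coords[r + 2L, ], g$len_ca_c, g$ang_n_ca_c,
                                   phi[i])
  }
  if (is.null(aa_seq)) aa_seq <- strrep("A", n)
  aa1 <- pb_letters(aa_seq)
  stopifnot(length(aa1) == n)
  out <- tibble::tibble(
    chain = chain_id,
    resno = seq_len(n),
    resname = aa_123(aa1),
    aa = aa1
  )
  idx <- function(k) coords[3L * (seq_len(n) - 1L) + k, , drop = FALSE]
  for (k in 1:3) {
    atom <- c("n", "ca", "c")[k]
    m <- idx(k)
    out[[paste0(atom, "_x")]] <- m[, 1]
    out[[paste0(atom, "_y")]] <- m[, 2]
    out[[paste0(atom, "_z")]] <- m[, 3]
  }
  out$complete <- TRUE
  out
}

# Place D given A-B-C, bond length |C-D|, bond angle B-C-D and torsion
# A-B-C-D (degrees): natural extension reference frame.
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- cross3(ab, bc)
  nv <- nv / sqrt(sum(nv^2))
  m <- cbind(bc, cross3(nv, bc), nv)
  as.numeric(m %*% d2 + c)
}

with_seed_if <- function(seed, expr) {
  expr <- substitute(expr)
  if (is.null(seed)) return(eval(expr, parent.frame()))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  eval(expr, parent.frame())
}

aa_123 <- function(aa1) {
  out <- suppressWarnings(bio3d::aa123(aa1))
  out[is.na(out) | out == "---"] <- "UNK"
  out
}

#' Write a backbone tibble as a PDB file
#'
#' Minimal ATOM/TER writer for fixture structures built with
#' [build_backbone()]; round-trips through [read_backbone()].
#'
#' @param chains A backbone tibble (one or more chains).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_backbone_pdb <- function(chains, file) {
  lines <- character(0)
  serial <- 0L
  for (ch in unique(chains$chain)) {
    sub <- chains[chains$chain == ch, ]
    # PDB chain field is one character; longer ids live in the file name
    ch <- if (nchar(ch) == 1L) ch else "A"
    for (i in seq_len(nrow(sub))) {
      for (atom in c("N", "CA", "C")) {
        xyz <- as.numeric(sub[i, paste(tolower(atom), c("x", "y", "z"),
                                       sep = "_")])
        if (any(is.na(xyz))) next
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", atom), " ", sub$resname[i], ch,
          sub$resno[i], " ", xyz[1], xyz[2], xyz[3], 1, 0))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Encode every chain of a structure file as PB and amino-acid sequences
#'
#' Convenience for knowledge-base construction: reads a PDB file, computes
#' phi/psi series per chain and encodes each into its PB sequence.
#'
#' @param file Path to a PDB file.
#' @param chain_id Optional identifier for single-chain files (defaults to
#'   the file name stem, suffixed with the chain letter when the file holds
#'   several chains).
#' @return A tibble with one row per chain: `chain`, `aa`, `pb`.
#' @export
encode_structure_file <- function(file, chain_id = NULL) {
  bb <- read_backbone(file)
  if (nrow(bb) == 0L) {
    return(tibble::tibble(chain = character(), aa = character(),
                          pb = character()))
  }
  stem <- chain_id %||% sub("\\.(pdb|ent)$", "", basename(file))
  chains <- unique(bb$chain)
  purrr::map_dfr(chains, function(ch) {
    sub <- bb[bb$chain == ch, ]
    id <- if (length(chains) == 1L) stem else paste0(stem, "_", ch)
    tibble::tibble(
      chain = id,
      aa = paste(sub$aa, collapse = ""),
      pb = encode_chain(phi_psi_series(sub))
    )
  })
}

#' Read and write FASTA files
#'
#' Thin wrappers used for amino-acid sequences and for PB sequences (alphabet
#' `a`-`p` plus `Z`; lowercase distinguishes PB strings from amino acids).
#' Parsing is plain-text and alphabet-agnostic.
#'
#' @param file Path to a FASTA file.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", file)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, file, width = 60L) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}
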