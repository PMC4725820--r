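# Double-stranded DNA model: a top-strand sequence with topology, per-base
# methylation marks and feature annotations.

empty_marks <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- tibble::new_tibble(
        list(position = integer(), strand = character(),
             kind = character(), source = character()), nrow = 0L)
    }
    cache
  }
})

empty_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- tibble::new_tibble(
        list(label = character(), start = integer(), end = integer(),
             strand = character(), type = character()), nrow = 0L)
    }
    cache
  }
})

# internal constructor bypassing revalidation on hot paths where the
# inputs are built from already-validated molecules
new_molecule_unsafe <- function(id, sequence, topology, marks, features) {
  structure(list(id = id, sequence = sequence, topology = topology,
                 marks = marks, features = features),
            class = "tnt_dna")
}

#' Create a DNA molecule
#'
#' A `tnt_dna` object models a linear or circular duplex by its top strand
#' (5'->3'), a set of per-base methylation marks and a table of features.
#' Coordinates are 0-based, half-open, on the top strand; on circular
#' molecules positions are taken modulo the length.
#'
#' @param id Text label.
#' @param sequence Top-strand sequence over A/C/G/T.
#' @param topology `"linear"` or `"circular"`.
#' @param marks Tibble with columns `position`, `strand` ("top"/"bottom"),
#'   `kind` ("m6A"/"m5C"), `source` (methyltransferase name).
#' @param features Tibble with columns `label`, `start`, `end`,
#'   `strand` ("+"/"-"), `type`.
#' @return A `tnt_dna` object.
#' @export
dna_molecule <- function(id, sequence, topology = c("linear", "circular"),
                         marks = empty_marks(), features = empty_features()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  assert_dna(sequence)
  if (!tibble::is_tibble(marks)) marks <- tibble::as_tibble(marks)
  if (!tibble::is_tibble(features)) features <- tibble::as_tibble(features)
  mol <- structure(
    list(id = as.character(id), sequence = sequence, topology = topology,
         marks = marks, features = features),
    class = "tnt_dna")
  validate_molecule(mol)
}

validate_molecule <- function(mol) {
  L <- nchar(mol$sequence)
  m <- mol$marks
  if (nrow(m)) {
    if (mol$topology == "circular") {
      m$position <- m$position %% L
      mol$marks <- m
    } else if (any(m$position < 0L | m$position >= L)) {
      stop("mark position outside molecule", call. = FALSE)
    }
    if (!all(m$strand %in% c("top", "bottom"))) {
      stop("mark strand must be 'top' or 'bottom'", call. = FALSE)
    }
    if (!all(m$kind %in% c("m6A", "m5C"))) {
      stop("mark kind must be 'm6A' or 'm5C'", call. = FALSE)
    }
    base <- substring(mol$sequence, m$position + 1L, m$position + 1L)
    want <- ifelse(m$kind == "m6A",
                   ifelse(m$strand == "top", "A", "T"),
                   ifelse(m$strand == "top", "C", "G"))
    if (any(base != want)) {
      stop("methylation mark kind inconsistent with base at its position",
           call. = FALSE)
    }
  }
  mol
}

#' Length of a molecule in base pairs
#'
#' @param mol A `tnt_dna` molecule.
#' @return Integer length of the top strand.
#' @export
dna_length <- function(mol) nchar(mol$sequence)

is_circular <- function(mol) identical(mol$topology, "circular")

#' @export
print.tnt_dna <- function(x, ...) {
  cat(sprintf("<tnt_dna> %s: %d bp %s, %d mark(s), %d feature(s)\n",
              x$id, dna_length(x), x$topology, nrow(x$marks),
              nrow(x$features)))
  invisible(x)
}

# Remove all methylation marks: models propagation of the plasmid in a
# non-methylating strain, where marks laid down in vitro or in the
# M.TaqI-expressing host are lost.
#' Erase methylation marks
#'
#' Returns a copy of the molecule with all methylation marks removed,
#' modelling propagation in a strain without the corresponding
#' methyltransferase.
#'
#' @param mol A `tnt_dna` molecule.
#' @param source Optional methyltransferase name; only marks from that
#'   source are erased.
#' @return The molecule without the selected marks.
#' @export
erase_marks <- function(mol, source = NULL) {
  if (is.null(source)) {
    mol$marks <- empty_marks()
  } else {
    mol$marks <- mol$marks[mol$marks$source != source, , drop = FALSE]
  }
  mol
}

# Rotate a circular molecule so old position k becomes position 0.
rotate_molecule <- function(mol, k) {
  if (!is_circular(mol)) stop("can only rotate circular molecules",
                              call. = FALSE)
  L <- dna_length(mol)
  k <- ((k %% L) + L) %% L
  if (k == 0L) return(mol)
  mol$sequence <- paste0(substr(mol$sequence, k + 1L, L),
                         substr(mol$sequence, 1L, k))
  if (nrow(mol$marks)) {
    mol$marks$position <- (mol$marks$position - k) %% L
  }
  if (nrow(mol$features)) {
    mol$features$start <- (mol$features$start - k) %% L
    mol$features$end <- (mol$features$end - k - 1L) %% L + 1L
    # features that now wrap the origin are dropped (annotations only)
    keep <- mol$features$start < mol$features$end
    mol$features <- mol$features[keep, , drop = FALSE]
  }
  mol
}

# Reverse complement of a whole molecule, remapping marks and features.
reverse_complement_molecule <- function(mol) {
  L <- dna_length(mol)
  mol$sequence <- rc(mol$sequence)
  if (nrow(mol$marks)) {
    mol$marks$position <- L - 1L - mol$marks$position
    mol$marks$strand <- ifelse(mol$marks$strand == "top", "bottom", "top")
  }
  if (nrow(mol$features)) {
    new_start <- L - mol$features$end
    new_end <- L - mol$features$start
    mol$features$start <- new_start
    mol$features$end <- new_end
    mol$features$strand <- ifelse(mol$features$strand == "+", "-", "+")
  }
  mol
}

#' Find motif occurrences in a molecule
#'
#' Scans for a motif (IUPAC codes allowed) on one or both strands. Hits are
#' reported by the 0-based top-strand start of the occurrence (leftmost
#' coordinate) together with the strand carrying the motif, in deterministic
#' ascending order. On circular molecules the scan wraps across the origin
#' and each physical occurrence is reported exactly once.
#'
#' @param mol A `tnt_dna` molecule.
#' @param motif Motif string (IUPAC alphabet).
#' @param strands `"both"`, `"top"` or `"bottom"`.
#' @return Tibble with columns `start`, `strand`, `motif`.
#' @export
find_motifs <- function(mol, motif, strands = c("both", "top", "bottom")) {
  strands <- match.arg(strands)
  if (!nchar(motif)) stop("motif must be non-empty", call. = FALSE)
  circ <- is_circular(mol)
  out <- list()
  if (strands %in% c("both", "top")) {
    s <- scan_string(mol$sequence, motif, circular = circ)
    if (length(s)) out$top <- quick_tbl(start = s,
                                        strand = rep("top", length(s)))
  }
  if (strands %in% c("both", "bottom")) {
    s <- scan_string(mol$sequence, rc(motif), circular = circ)
    if (length(s)) out$bottom <- quick_tbl(start = s,
                                           strand = rep("bottom", length(s)))
  }
  if (!length(out)) {
    return(quick_tbl(start = integer(), strand = character(),
                     motif = character()))
  }
  hits <- quick_bind(unname(out))
  hits$motif <- rep(toupper(motif), nrow(hits))
  hits[order(hits$start, hits$strand), ]
}
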