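# Format round-trips. FASTA goes through Biostrings; GenBank uses a
# minimal flat-file writer/reader covering what the simulator stores:
# LOCUS topology, misc_feature annotations (with label/type/strand notes),
# methylation marks serialised as misc_feature notes, and the ORIGIN block.

#' Write molecules to FASTA
#'
#' Topology is recorded in the header as `topology=circular|linear` so a
#' round-trip preserves it.
#'
#' @param mols A `tnt_dna` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(mols, path) {
  if (inherits(mols, "tnt_dna")) mols <- list(mols)
  set <- Biostrings::DNAStringSet(vapply(mols, function(m) m$sequence,
                                         character(1)))
  names(set) <- vapply(mols, function(m)
    paste0(m$id, " topology=", m$topology), character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read molecules from FASTA
#'
#' @param path FASTA file.
#' @return List of `tnt_dna` molecules.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    topo <- if (grepl("topology=circular", header)) "circular" else "linear"
    id <- sub("\\s.*$", "", header)
    dna_molecule(id, as.character(set[[i]]), topo)
  })
}

GENBANK_DATE <- "01-JAN-2026" # fixed so write->read->write is a fixpoint

#' Write a molecule to a GenBank record
#'
#' Features become `misc_feature` entries with `/label` and a `/note`
#' carrying the feature type; methylation marks are serialised as
#' single-base `misc_feature`s with a `methyl:` note. Topology is encoded
#' in the LOCUS line.
#'
#' @param mol A `tnt_dna`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(mol, path) {
  L <- dna_length(mol)
  lines <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     mol$id, L, mol$topology, GENBANK_DATE),
             sprintf("DEFINITION  %s.", mol$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  fmt_feat <- function(loc, quals) {
    c(sprintf("     misc_feature    %s", loc),
      sprintf("                     %s", quals))
  }
  if (nrow(mol$features)) {
    for (i in seq_len(nrow(mol$features))) {
      f <- mol$features[i, ]
      loc <- sprintf("%d..%d", f$start + 1L, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines, fmt_feat(loc, c(
        sprintf("/label=\"%s\"", f$label),
        sprintf("/note=\"type:%s\"", f$type))))
    }
  }
  if (nrow(mol$marks)) {
    for (i in seq_len(nrow(mol$marks))) {
      m <- mol$marks[i, ]
      lines <- c(lines, fmt_feat(sprintf("%d", m$position + 1L),
                                 sprintf("/note=\"methyl:%s:%s:%s\"",
                                         m$kind, m$strand, m$source)))
    }
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(mol$sequence, s, min(s + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s,
                              paste(tolower(groups), collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank record written by [write_genbank()]
#'
#' @param path GenBank file.
#' @return A `tnt_dna` molecule.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  if (is.na(locus)) stop("parse error in ", path, " line 1: no LOCUS line",
                         call. = FALSE)
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]]
  id <- toks[1]
  topology <- if (any(toks == "circular")) "circular" else "linear"
  origin_at <- which(grepl("^ORIGIN", lines))
  if (!length(origin_at)) stop("parse error in ", path, ": no ORIGIN block",
                               call. = FALSE)
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seqs <- toupper(gsub("[^acgtACGT]", "", seq_lines))
  sequence <- paste0(seqs, collapse = "")
  feats <- empty_features()
  marks <- empty_marks()
  i <- 1L
  while (i < origin_at) {
    line <- lines[i]
    if (grepl("^\\s{5}misc_feature", line)) {
      loc <- trimws(sub("^\\s{5}misc_feature\\s+", "", line))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      label <- NA_character_
      note <- NA_character_
      j <- i + 1L
      while (j < origin_at && grepl("^\\s{21}", lines[j])) {
        q <- trimws(lines[j])
        if (grepl("^/label=", q)) label <- gsub("^/label=\"|\"$", "", q)
        if (grepl("^/note=", q)) note <- gsub("^/note=\"|\"$", "", q)
        j <- j + 1L
      }
      if (!is.na(note) && grepl("^methyl:", note)) {
        parts <- strsplit(note, ":")[[1]]
        marks <- dplyr::bind_rows(marks, tibble::tibble(
          position = as.integer(loc) - 1L, strand = parts[3],
          kind = parts[2], source = parts[4]))
      } else {
        ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        type <- if (!is.na(note) && grepl("^type:", note))
          sub("^type:", "", note) else "misc"
        feats <- dplyr::bind_rows(feats, tibble::tibble(
          label = label, start = ab[1] - 1L, end = ab[2],
          strand = strand, type = type))
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  dna_molecule(id, sequence, topology, marks = marks, features = feats)
}
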