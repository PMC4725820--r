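# Internal-site management: scanning for (G)CTCTTC sites, synonymous
# recoding of coding sequences (domestication), design of 26-nt masking
# oligos (BlindSpot) with specificity triage, and the partial-digestion
# BlindSpot protocol simulation.

# E. coli codon preference, most common codon first, per amino acid.
# Used as the deterministic tie-break when several synonymous edits
# remove a site.
CODON_PREFERENCE <- list(
  A = c("GCG", "GCC", "GCA", "GCT"),
  R = c("CGC", "CGT", "CGG", "CGA", "AGA", "AGG"),
  N = c("AAC", "AAT"),
  D = c("GAT", "GAC"),
  C = c("TGC", "TGT"),
  Q = c("CAG", "CAA"),
  E = c("GAA", "GAG"),
  G = c("GGC", "GGT", "GGG", "GGA"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("CTG", "TTA", "TTG", "CTT", "CTC", "CTA"),
  K = c("AAA", "AAG"),
  M = "ATG",
  F = c("TTT", "TTC"),
  P = c("CCG", "CCA", "CCT", "CCC"),
  S = c("AGC", "TCG", "TCT", "TCC", "AGT", "TCA"),
  T = c("ACC", "ACG", "ACT", "ACA"),
  W = "TGG",
  Y = c("TAT", "TAC"),
  V = c("GTG", "GTT", "GTC", "GTA"),
  "*" = c("TAA", "TGA", "TAG"))

SITE_MOTIF_TOP <- "CTCTTC"
SITE_MOTIF_BOTTOM <- "GAAGAG" # the bottom-strand representation

#' Scan a sequence for internal recognition sites
#'
#' Finds every physical (G)CTCTTC site: CTCTTC occurrences on the given
#' strand and GAAGAG occurrences (the same motif class carried by the
#' bottom strand), deduplicated per physical site. A hit is flagged
#' `extended` when the nested 7-nt LguI form (GCTCTTC / GAAGAGC) is
#' present. The 26-nt masking-oligo window (11 nt upstream of the 7-nt
#' site window, 8 nt downstream, on the strand reading 5'GCTCTTC3') is
#' reported, with a truncation flag near sequence ends.
#'
#' @param seq A DNA string or `tnt_dna` molecule.
#' @param frame Optional reading frame (recorded, not used for scanning).
#' @return Tibble of site hits.
#' @export
scan_internal_sites <- function(seq, frame = NULL) {
  if (inherits(seq, "tnt_dna")) seq <- seq$sequence
  assert_dna(seq)
  L <- nchar(seq)
  rows <- list()
  for (s in scan_string(seq, SITE_MOTIF_TOP)) {
    ext <- s >= 1L && substr(seq, s, s) == "G"
    win_start <- s - 12L
    win_end <- s + 14L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      start = s, strand = "top", motif = SITE_MOTIF_TOP, extended = ext,
      window_start = win_start, window_end = win_end)
  }
  for (s in scan_string(seq, SITE_MOTIF_BOTTOM)) {
    ext <- s + 6L < L && substr(seq, s + 7L, s + 7L) == "C"
    win_start <- s - 8L
    win_end <- s + 18L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      start = s, strand = "bottom", motif = SITE_MOTIF_BOTTOM,
      extended = ext, window_start = win_start, window_end = win_end)
  }
  if (!length(rows)) {
    return(tibble::tibble(start = integer(), strand = character(),
                          motif = character(), extended = logical(),
                          window_start = integer(), window_end = integer(),
                          truncated = logical(), context = character()))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$start), , drop = FALSE]
  out$truncated <- out$window_start < 0L | out$window_end > L
  out$context <- NA_character_
  full <- !out$truncated
  if (any(full)) {
    win <- substring(seq, out$window_start[full] + 1L, out$window_end[full])
    flipme <- out$strand[full] == "bottom"
    win[flipme] <- vapply(win[flipme], rc, character(1), USE.NAMES = FALSE)
    out$context[full] <- win
  }
  out
}

#' Domesticate a coding sequence
#'
#' Synonymously recodes a CDS until it contains no CTCTTC or GAAGAG site.
#' Each removable site costs exactly one codon edit; candidate edits are
#' ranked by the preference rank of the replacement codon within its amino
#' acid (most common codon first), then by codon position, making the
#' result deterministic. An edit never introduces a new site. Sites that
#' no synonymous choice can remove raise an `undomesticatable-site` error
#' (fall back to the BlindSpot route).
#'
#' @param cds DNA string; length must be a multiple of 3 with no internal
#'   stop codon.
#' @return List with `sequence` (recoded CDS) and `edits` (tibble:
#'   codon_index (1-based), old, new, aa, site_position).
#' @export
domesticate <- function(cds) {
  assert_dna(cds, "cds")
  if (nchar(cds) %% 3L != 0L) {
    stop("cds length must be a multiple of 3", call. = FALSE)
  }
  prot <- translate_dna(cds)
  if (grepl("\\*", substr(prot, 1L, nchar(prot) - 1L))) {
    stop("cds contains an internal stop codon", call. = FALSE)
  }
  edits <- list()
  current <- cds
  repeat {
    sites <- sort(unique(c(scan_string(current, SITE_MOTIF_TOP),
                           scan_string(current, SITE_MOTIF_BOTTOM))))
    if (!length(sites)) break
    s <- sites[1]
    cand <- site_edit_candidates(current, s, sites)
    if (is.null(cand)) {
      stop(sprintf("undomesticatable-site at position %d", s),
           call. = FALSE)
    }
    current <- cand$sequence
    edits[[length(edits) + 1L]] <- tibble::tibble(
      codon_index = cand$codon_index, old = cand$old, new = cand$new,
      aa = cand$aa, site_position = s)
  }
  list(sequence = current,
       edits = if (length(edits)) dplyr::bind_rows(edits) else
         tibble::tibble(codon_index = integer(), old = character(),
                        new = character(), aa = character(),
                        site_position = integer()))
}

site_edit_candidates <- function(cds, s, old_sites) {
  first_codon <- s %/% 3L
  last_codon <- (s + 5L) %/% 3L
  best <- NULL
  for (ci in first_codon:last_codon) {
    if ((ci + 1L) * 3L > nchar(cds)) next
    old_codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
    aa <- unname(Biostrings::GENETIC_CODE[old_codon])
    alts <- CODON_PREFERENCE[[aa]]
    for (rank in seq_along(alts)) {
      new_codon <- alts[rank]
      if (new_codon == old_codon) next
      trial <- cds
      substr(trial, ci * 3L + 1L, ci * 3L + 3L) <- new_codon
      new_sites <- sort(unique(c(scan_string(trial, SITE_MOTIF_TOP),
                                 scan_string(trial, SITE_MOTIF_BOTTOM))))
      if (s %in% new_sites) next            # site not removed
      if (!all(new_sites %in% old_sites)) next # new site introduced
      cand <- list(sequence = trial, codon_index = ci + 1L,
                   old = old_codon, new = new_codon, aa = aa,
                   rank = rank)
      if (is.null(best) ||
          rank < best$rank ||
          (rank == best$rank && ci + 1L < best$codon_index) ||
          (rank == best$rank && ci + 1L == best$codon_index &&
             new_codon < best$new)) {
        best <- cand
      }
      break # alternatives for this codon are ranked; first hit is best
    }
  }
  best
}

# -- BlindSpot oligo design --------------------------------------------------

#' Design a BlindSpot masking oligo
#'
#' Designs the 26-nt DNA oligo that masks one internal (G)CTCTTC site
#' during partial digestion: 11 nt upstream of the 7-nt site window and
#' 8 nt downstream (covering the cleavage site), taken from the strand
#' reading 5'GCTCTTC3' (if the sense strand reads 5'GAAGAGC3', the
#' antisense strand is used). The mismatch profile against every other
#' site's window is reported; windows with fewer than `min_mismatches`
#' differences to a must-cut site trigger a specificity warning.
#'
#' @param seq DNA string or `tnt_dna` molecule containing the sites.
#' @param target One row of [scan_internal_sites()] output (the site to
#'   mask).
#' @param all_sites Full [scan_internal_sites()] table (defaults to
#'   re-scanning `seq`).
#' @param min_mismatches Specificity floor (default 4).
#' @return List with `sequence` (26 nt), `target`, `orientation`,
#'   `mismatch_profile` (tibble) and `warnings` (character).
#' @export
design_blindspot <- function(seq, target, all_sites = NULL,
                             min_mismatches = 4L) {
  if (inherits(seq, "tnt_dna")) seq <- seq$sequence
  target <- as.list(tibble::as_tibble(target)[1, ])
  if (is.null(all_sites)) all_sites <- scan_internal_sites(seq)
  if (isTRUE(target$truncated) || is.na(target$context)) {
    stop("target flanks are shorter than the 11/8 nt needed for the oligo",
         call. = FALSE)
  }
  oligo <- target$context
  stopifnot(nchar(oligo) == 26L)
  others <- all_sites[!(all_sites$start == target$start &
                          all_sites$strand == target$strand), ,
                      drop = FALSE]
  profile <- tibble::tibble(start = integer(), strand = character(),
                            mismatches = integer())
  warnings <- character()
  if (nrow(others)) {
    mm <- vapply(seq_len(nrow(others)), function(i) {
      ctx <- others$context[i]
      if (is.na(ctx)) return(NA_integer_)
      hamming(oligo, ctx)
    }, integer(1))
    profile <- tibble::tibble(start = others$start,
                              strand = others$strand, mismatches = mm)
    close_idx <- which(!is.na(mm) & mm < min_mismatches)
    if (length(close_idx)) {
      warnings <- sprintf(
        "site at %d (%s) has only %d mismatch(es) to the oligo window (specificity floor: %d)",
        others$start[close_idx], others$strand[close_idx], mm[close_idx],
        min_mismatches)
    }
  }
  list(sequence = oligo,
       target = tibble::as_tibble(target),
       orientation = if (target$strand == "top") "sense" else "antisense",
       mismatch_profile = profile, warnings = warnings)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Inhibition coefficient
#'
#' The specificity margin of a masking oligo: percentage inhibition at the
#' matched (masked) site minus percentage inhibition at a mismatched
#' (must-cut) site.
#'
#' @param inhibition_matched,inhibition_mismatched Percentages in
#'   \[0, 100\].
#' @return Difference, in percentage points.
#' @examples
#' inhibition_coefficient(75.9, 8.3) # 67.6
#' @export
inhibition_coefficient <- function(inhibition_matched,
                                   inhibition_mismatched) {
  stopifnot(inhibition_matched >= 0, inhibition_matched <= 100,
            inhibition_mismatched >= 0, inhibition_mismatched <= 100)
  inhibition_matched - inhibition_mismatched
}

#' Simulate the BlindSpot partial-digestion protocol
#'
#' Simulates `n` molecules of a template through a partial digestion in
#' which protected (oligo-masked) sites cut with probability
#' `p_cut * (1 - inhibition)` and every other site with `p_cut`, then
#' scores the fraction of molecules whose digestion pattern yields the
#' intended product: all vector (non-protected) sites cut, the insert's
#' internal sites intact.
#'
#' @param mol Template `tnt_dna` molecule.
#' @param enzyme A `tnt_enzyme` or name.
#' @param protected_sites Integer vector of `cut_top` coordinates of the
#'   masked internal sites.
#' @param p_cut Per-site cut probability of the partial digestion
#'   (default 0.625, the midpoint of a 60-65% digestion progress).
#' @param inhibition Fractional inhibition at masked sites in \[0,1\]
#'   (default 0.759 for a matched LguI oligo; use 0.499 for EarI).
#' @param n Number of molecules to simulate.
#' @param seed RNG seed.
#' @return List with `site_summary` (per-site empirical cut fractions),
#'   `frac_intended` (unconditional), `frac_intended_given_vector_cut`
#'   (conditional on all vector sites cut), and `n`.
#' @export
simulate_blindspot <- function(mol, enzyme, protected_sites,
                               p_cut = 0.625, inhibition = 0.759,
                               n = 10000L, seed = 1L) {
  stopifnot(inhibition >= 0, inhibition <= 1, p_cut >= 0, p_cut <= 1)
  if (is.character(enzyme)) enzyme <- tnt_enzyme(enzyme)
  sites <- list_cut_sites(mol, enzyme)
  sites <- sites[!sites$blocked & sites$status == "ok", , drop = FALSE]
  cuts <- sort(unique(sites$cut_top))
  if (!all(protected_sites %in% cuts)) {
    stop("unknown protected site key(s): ",
         paste(setdiff(protected_sites, cuts), collapse = ", "),
         call. = FALSE)
  }
  k <- length(cuts)
  protected <- cuts %in% protected_sites
  probs <- ifelse(protected, p_cut * (1 - inhibition), p_cut)
  with_private_seed(seed, {
    u <- matrix(stats::runif(n * k), nrow = n)
  })
  cut_mat <- sweep(u, 2L, probs, "<")
  vector_ok <- if (any(!protected)) {
    rowSums(cut_mat[, !protected, drop = FALSE]) == sum(!protected)
  } else rep(TRUE, n)
  insert_ok <- if (any(protected)) {
    rowSums(cut_mat[, protected, drop = FALSE]) == 0L
  } else rep(TRUE, n)
  intended <- vector_ok & insert_ok
  list(
    site_summary = tibble::tibble(
      cut_top = cuts, protected = protected, probability = probs,
      cut_fraction = colMeans(cut_mat)),
    frac_intended = mean(intended),
    frac_intended_given_vector_cut =
      if (any(vector_ok)) mean(intended) / mean(vector_ok) else NA_real_,
    n = n)
}
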