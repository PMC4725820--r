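# Shared fixtures and independent oracles for the test suite.

tnt_registry <- build_registry()

# brute-force canonicalisation: lexicographically least rotation of a
# circular sequence or its reverse complement (independent of the
# package's internal canonicalisation)
oracle_canon <- function(seq) {
  L <- nchar(seq)
  rots <- function(s) {
    ss <- paste0(s, s)
    vapply(seq_len(L), function(i) substr(ss, i, i + L - 1L), character(1))
  }
  rcseq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  min(c(rots(seq), rots(rcseq)))
}

oracle_rc <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Brute-force enumeration of all circular ligation products of a fragment
# list: every subset, ordering and orientation assignment is checked for
# cyclic Watson-Crick closure of the 3-nt overhangs. Returns the set of
# canonical product sequences.
oracle_circles <- function(frags) {
  n <- length(frags)
  ends <- lapply(frags, function(f) {
    list(fwd = list(left = f$left_ov, right = f$right_ov,
                    top = paste0(f$left_ov, f$core)),
         rev = list(left = f$right_ov, right = f$left_ov,
                    top = oracle_rc(paste0(f$left_ov, f$core,
                                           oracle_rc(f$right_ov)))))
  })
  # the flipped top strand must drop the region that becomes the new
  # right overhang (single-stranded on the other side)
  for (i in seq_len(n)) {
    full <- ends[[i]]$rev$top
    ends[[i]]$rev$top <- substr(full, 1L, nchar(full) - 3L)
  }
  found <- character()
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (size in seq_len(n)) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    for (sub in subsets) {
      for (ord in perms(sub)) {
        if (length(ord) > 1L && ord[1] != min(ord)) next # fix rotation
        n_or <- length(ord)
        for (mask in 0:(2 ^ n_or - 1L)) {
          orient <- bitwAnd(mask, 2 ^ (seq_len(n_or) - 1L)) > 0
          es <- lapply(seq_len(n_or), function(k) {
            if (orient[k]) ends[[ord[k]]]$rev else ends[[ord[k]]]$fwd
          })
          ok <- all(vapply(seq_len(n_or), function(k) {
            nxt <- es[[k %% n_or + 1L]]
            nchar(es[[k]]$right) == 3L &&
              identical(oracle_rc(es[[k]]$right), nxt$left)
          }, logical(1)))
          if (ok) {
            seqs <- paste0(vapply(es, function(e) e$top, character(1)),
                           collapse = "")
            found <- c(found, oracle_canon(seqs))
          }
        }
      }
    }
  }
  sort(unique(found))
}

product_canon <- function(products) {
  sort(unique(vapply(products, function(p)
    oracle_canon(p$molecule$sequence), character(1))))
}

# random sticky fragment with given overhangs
random_fragment <- function(left, right, core_len = 30L) {
  tntsim:::new_fragment(
    core = paste0(sample(c("A", "C", "G", "T"), core_len, replace = TRUE),
                  collapse = ""),
    left_ov = left, right_ov = right)
}

random_cds_with_sites <- function(n_codons = 60L, n_sites = 2L) {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  repeat {
    seqs <- paste0(sample(codons, n_codons, replace = TRUE), collapse = "")
    # plant motifs at codon boundaries (Leu-Phe / Glu-Glu readings)
    spots <- sample(seq_len(n_codons - 2L), n_sites) * 3L
    for (k in seq_len(n_sites)) {
      motif <- sample(c("CTCTTC", "GAAGAG"), 1L)
      substr(seqs, spots[k] + 1L, spots[k] + 6L) <- motif
    }
    prot <- translate_dna(seqs)
    if (!grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)) &&
        length(tntsim:::scan_string(seqs, "CTCTTC")) +
        length(tntsim:::scan_string(seqs, "GAAGAG")) >= 1L) {
      return(seqs)
    }
  }
}
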