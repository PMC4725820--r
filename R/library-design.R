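# Library-entry design: element records and validation, entry-primer
# design from the fixed library templates, nearest-neighbour melting
# temperature model, and the polycistronic split-efficiency arithmetic.

ELEMENT_CATEGORIES <- c("URR", "UTR", "CDS", "terminator",
                        "localization-signal", "tag", "scaffold",
                        "structural")

FWD_PRIMER_PREFIX <- "ACATGCAGCTCTTCCACC"
REV_PRIMER_PREFIX <- "CGAGGAAGCTCTTCCATC"

#' Create an element record
#'
#' @param id Element id.
#' @param sequence DNA sequence (5'->3', sense orientation).
#' @param category One of URR, UTR, CDS, terminator, localization-signal,
#'   tag, scaffold, structural.
#' @param domesticated Whether internal sites were already recoded.
#' @return A `tnt_element` object (also a `tnt_dna` molecule).
#' @export
element_record <- function(id, sequence, category = "CDS",
                           domesticated = FALSE) {
  category <- match.arg(category, ELEMENT_CATEGORIES)
  mol <- dna_molecule(id, sequence, "linear")
  mol$category <- category
  mol$domesticated <- domesticated
  mol$internal_sites <- scan_internal_sites(mol$sequence)
  class(mol) <- c("tnt_element", class(mol))
  mol
}

#' Validate an element for library entry
#'
#' CDS elements must be a multiple of 3 long and stop-free (stop codons
#' belong in the terminator/3'UTR elements). Internal (G)CTCTTC sites do
#' not reject an element but earn remediation advice: synonymous recoding
#' for a CDS, the BlindSpot masking route otherwise.
#'
#' @param element A `tnt_element` (or any `tnt_dna` with a `category`).
#' @return Tibble with columns `id`, `category`, `status`
#'   (`"pass"`/`"reject"`), `n_internal_sites`, `advice`.
#' @export
validate_element <- function(element) {
  category <- element$category %||% "CDS"
  seq <- element$sequence
  sites <- scan_internal_sites(seq)
  status <- "pass"
  advice <- character()
  if (category == "CDS") {
    if (nchar(seq) %% 3L != 0L) {
      status <- "reject"
      advice <- c(advice, "CDS length is not a multiple of 3")
    } else {
      prot <- translate_dna(seq)
      internal <- substr(prot, 1L, nchar(prot) - 1L)
      stop_at <- regexpr("\\*", internal)
      if (stop_at > 0L) {
        status <- "reject"
        advice <- c(advice, sprintf(
          "internal stop codon at codon %d (nt %d); stops belong in the terminator/3'UTR",
          stop_at, (stop_at - 1L) * 3L))
      }
    }
  }
  if (status == "pass" && nrow(sites)) {
    advice <- c(advice, if (category == "CDS") {
      "internal (G)CTCTTC site(s): domesticate() before library entry"
    } else {
      "internal (G)CTCTTC site(s): use the BlindSpot masking route when assembling"
    })
  }
  tibble::tibble(id = element$id, category = category, status = status,
                 n_internal_sites = nrow(sites),
                 advice = paste(advice, collapse = "; "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- melting temperature -----------------------------------------------------

# Unified nearest-neighbour parameters (dH kcal/mol, dS cal/mol/K)
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbour melting temperature
#'
#' Two-state nearest-neighbour Tm with duplex-initiation terms, an entropic
#' salt correction of `0.368 (N-1) ln[Na+]`, and the oligo concentration
#' entering as `R ln(C/4)` for non-self-complementary duplexes.
#'
#' @param seq Primer sequence (5'->3').
#' @param na_molar Monovalent salt concentration (default 0.05 M).
#' @param oligo_molar Total oligo concentration (default 5e-7 M).
#' @return Tm in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(seq, na_molar = 0.05, oligo_molar = 5e-7) {
  assert_dna(seq, "primer")
  n <- nchar(seq)
  if (n < 2L) stop("primer too short for a nearest-neighbour model",
                   call. = FALSE)
  pairs <- substring(seq, seq_len(n - 1L), 2:n)
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  for (termini in c(substr(seq, 1, 1), substr(seq, n, n))) {
    if (termini %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_molar)
  tm_k <- (dh * 1000) / (ds + 1.9872 * log(oligo_molar / 4))
  tm_k - 273.15
}

#' Design library-entry primers for an element
#'
#' Forward and reverse primers follow the fixed library templates: the
#' forward primer is `ACATGCAGCTCTTCCACC` + annealing region (the prefix
#' carries the LguI site, a 1-nt spacer and signature 1), the reverse is
#' `CGAGGAAGCTCTTCCATC` + annealing region (signature 2). Annealing
#' regions start at 20 nt of the element's 5' end (forward) or of the
#' reverse complement of its 3' end (reverse) and are extended one
#' nucleotide at a time until the melting temperature reaches `tm_min`.
#'
#' @param element A `tnt_element`/`tnt_dna` or DNA string.
#' @param tm_min Minimum annealing Tm in degrees Celsius (default 50).
#' @param na_molar,oligo_molar Passed to [tm_nearest_neighbor()].
#' @return Tibble with the two primers, their annealing lengths and Tm
#'   values; the Tm model parameters are attached as attribute
#'   `"tm_model"`.
#' @export
design_entry_primers <- function(element, tm_min = 50,
                                 na_molar = 0.05, oligo_molar = 5e-7) {
  seq <- if (inherits(element, "tnt_dna")) element$sequence else element
  assert_dna(seq, "element")
  if (nchar(seq) < 40L) {
    stop("element too short (< 40 nt) for primer design", call. = FALSE)
  }
  anneal <- function(template) {
    len <- 20L
    repeat {
      if (len > nchar(template)) {
        stop("element exhausted before reaching the minimum Tm; ",
             "consider synthesising the fragment", call. = FALSE)
      }
      region <- substr(template, 1L, len)
      tm <- tm_nearest_neighbor(region, na_molar, oligo_molar)
      if (tm >= tm_min) return(list(region = region, tm = tm, len = len))
      len <- len + 1L
    }
  }
  fwd <- anneal(seq)
  rev <- anneal(rc(seq))
  out <- tibble::tibble(
    primer = c("forward", "reverse"),
    sequence = c(paste0(FWD_PRIMER_PREFIX, fwd$region),
                 paste0(REV_PRIMER_PREFIX, rev$region)),
    annealing_length = c(fwd$len, rev$len),
    annealing_tm = c(fwd$tm, rev$tm))
  attr(out, "tm_model") <- list(model = "nearest-neighbor (unified)",
                                na_molar = na_molar,
                                oligo_molar = oligo_molar,
                                tm_min = tm_min)
  out
}

#' Simulated PCR product of the entry primers
#'
#' The linear amplicon a primer pair produces from its element: forward
#' prefix + element + reverse complement of the reverse prefix. Digesting
#' it with LguI releases the element flanked by the s1/s2 overhangs.
#'
#' @param element `tnt_element`/`tnt_dna` or DNA string.
#' @param primers Result of [design_entry_primers()] (optional; only the
#'   fixed prefixes matter for the product structure).
#' @return Linear `tnt_dna` amplicon.
#' @export
entry_pcr_product <- function(element, primers = NULL) {
  seq <- if (inherits(element, "tnt_dna")) element$sequence else element
  id <- if (inherits(element, "tnt_dna")) element$id else "element"
  amplicon <- paste0(FWD_PRIMER_PREFIX, seq, rc(REV_PRIMER_PREFIX))
  dna_molecule(paste0("amplicon:", id), amplicon, "linear",
               features = tibble::tibble(
                 label = id, start = nchar(FWD_PRIMER_PREFIX),
                 end = nchar(FWD_PRIMER_PREFIX) + nchar(seq),
                 strand = "+", type = "element"))
}

# -- polycistron arithmetic --------------------------------------------------

#' Polycistronic split efficiency
#'
#' With `n_genes` coding sequences sharing one mRNA separated by
#' self-splicing junctions of per-junction efficiency `per_junction_eff`,
#' the fraction of transcripts with every junction correctly split is
#' `per_junction_eff^(n_genes - 1)`.
#'
#' @param per_junction_eff Per-junction split efficiency in \[0,1\].
#' @param n_genes Number of genes on the mRNA (>= 1).
#' @return Fraction in \[0,1\].
#' @examples
#' polycistron_efficiency(0.997, 10) # ~0.973
#' @export
polycistron_efficiency <- function(per_junction_eff, n_genes) {
  stopifnot(per_junction_eff >= 0, per_junction_eff <= 1, n_genes >= 1)
  per_junction_eff ^ (n_genes - 1)
}

#' Residual flaw of tandem self-splicing elements
#'
#' Stacking `copies` independent copies of an element whose single-copy
#' flaw rate is `flaw` reduces the residual flaw to `flaw^copies`
#' (e.g. 20% with one copy becomes 4% with two).
#'
#' @param flaw Single-copy flaw fraction in \[0,1\].
#' @param copies Number of tandem copies (>= 1).
#' @return Residual flaw fraction.
#' @export
flaw_stacking <- function(flaw, copies) {
  stopifnot(flaw >= 0, flaw <= 1, copies >= 1)
  flaw ^ copies
}
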