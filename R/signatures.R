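# The 3-nt signature grammar. Signatures direct fragment order and
# orientation at ligation; their length (3 nt, one codon) is what keeps
# reading frames intact across junctions.
#
# Reading convention: each signature is stored 5'->3' as read on the strand
# that carries it in the primer/vector design. Signature 1 is read on the
# top strand at its junction; signature 2 on the bottom strand (as in the
# reverse library primer); signatures 3 and 4 are stored as their
# top-strand junction 3-mers. `junction_tops()` converts all of them to the
# top-strand 3-mer seen at the assembled junction.

#' Create a signature set
#'
#' @param s1,s2,s3,s4 Core signatures (3-nt DNA strings; see Details).
#' @param s1R,s2R Labels recorded on the reversed-orientation accept
#'   junctions of the R vector members.
#' @details Constraints enforced: all six values pairwise distinct, none
#'   the reverse complement of another (which would allow unintended
#'   cross-ligation), all starting with adenine (so that the TCGA overlap
#'   protecting composite release sites can form), and s3/s4 ending with T
#'   (their reverse reading must also start with adenine, because both
#'   occur on right-hand release flanks of protected sites).
#' @return A `tnt_signature_set`.
#' @export
signature_set <- function(s1 = "ACC", s2 = "ATC", s3 = "AAT", s4 = "ACT",
                          s1R = "ACG", s2R = "ATG") {
  sigs <- list(s1 = toupper(s1), s2 = toupper(s2), s3 = toupper(s3),
               s4 = toupper(s4), s1R = toupper(s1R), s2R = toupper(s2R))
  problems <- character()
  for (nm in names(sigs)) {
    v <- sigs[[nm]]
    if (nchar(v) != 3L || grepl("[^ACGT]", v)) {
      problems <- c(problems, sprintf("%s must be a 3-nt ACGT string", nm))
    }
  }
  if (!length(problems)) {
    vals <- unlist(sigs)
    if (anyDuplicated(vals)) {
      problems <- c(problems, "signatures must be pairwise distinct")
    }
    rcs <- vapply(vals, rc, character(1))
    for (i in seq_along(vals)) {
      for (j in seq_along(vals)) {
        if (i < j && vals[i] == rcs[j]) {
          problems <- c(problems, sprintf(
            "%s equals the reverse complement of %s (cross-ligation risk)",
            names(vals)[i], names(vals)[j]))
        }
      }
    }
    if (any(substr(vals, 1, 1) != "A")) {
      problems <- c(problems,
                    "every signature must start with adenine (TCGA-overlap rule)")
    }
    for (nm in c("s3", "s4")) {
      if (substr(sigs[[nm]], 3, 3) != "T") {
        problems <- c(problems, sprintf(
          "%s must end with T: it flanks protected sites on both sides", nm))
      }
    }
  }
  if (length(problems)) {
    stop("invalid signature set:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(sigs, class = "tnt_signature_set")
}

#' @export
print.tnt_signature_set <- function(x, ...) {
  cat("<tnt_signature_set>",
      paste(names(unclass(x)), unlist(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

# top-strand 3-mer at each assembled junction
junction_tops <- function(sigs) {
  c(s1 = sigs$s1, s2 = rc(sigs$s2), s3 = sigs$s3, s4 = sigs$s4)
}

# Accept junction tops of the reversed (R) members: capturing a standard
# s1/s2-flanked library insert in antisense orientation forces the exposed
# overhangs to be the reverse complements of the standard accept junctions.
# The configured s1R/s2R values label these junctions in annotations.
r_accept_junctions <- function(sigs) {
  J <- junction_tops(sigs)
  c(left = rc(J[["s2"]]), right = rc(J[["s1"]]))
}
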