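# Low-level string utilities shared by every module. Coordinates are 0-based,
# half-open, on the top strand throughout the package.

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

assert_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq)) {
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  }
  if (nchar(seq) < 1L) stop(sprintf("%s must be non-empty", what), call. = FALSE)
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop(sprintf("invalid-alphabet: %s contains non-ACGT character(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement on the A/C/G/T alphabet.
#' The operation is an involution and preserves length.
#'
#' @param seq A single DNA string (characters A, C, G, T only).
#' @return The reverse complement, as a character string.
#' @examples
#' reverse_complement("GCTCTTC") # "GAAGAGC"
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# internal fast path (input already validated); avoids S4 dispatch in the
# simulation inner loops, cross-checked against Biostrings in the tests
rc <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", seq))))
}

# fast tibble constructor for hot paths (columns already validated)
quick_tbl <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = length(cols[[1L]]))
}

# row-bind tibbles that share identical atomic columns (fast path)
quick_bind <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  if (length(lst) == 1L) return(lst[[1L]])
  nms <- names(lst[[1L]])
  cols <- lapply(nms, function(nm)
    unlist(lapply(lst, function(x) x[[nm]]), use.names = FALSE))
  names(cols) <- nms
  tibble::new_tibble(cols, nrow = length(cols[[1L]]))
}

iupac_to_regex <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_REGEX))
  if (length(bad)) {
    stop("invalid-alphabet: motif contains non-IUPAC character(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste0(IUPAC_REGEX[letters], collapse = "")
}

# 0-based starts of (possibly overlapping) motif matches on a plain string.
# For circular = TRUE the scan wraps across the origin; each physical
# occurrence is reported exactly once, with start taken modulo length.
scan_string <- function(seq, motif, circular = FALSE) {
  m <- nchar(motif)
  L <- nchar(seq)
  subject <- seq
  if (circular && m > 1L) {
    subject <- paste0(seq, substr(seq, 1L, min(L, m - 1L)))
  }
  if (m > nchar(subject)) return(integer(0))
  rx <- paste0("(?=", iupac_to_regex(motif), ")")
  hits <- gregexpr(rx, subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  starts <- as.integer(hits) - 1L
  starts[starts < L]
}

#' Translate a DNA string
#'
#' Translates with the standard genetic code; stop codons are rendered as
#' `"*"` and a trailing partial codon is ignored.
#'
#' @param seq A DNA string.
#' @param frame Reading frame offset: 0, 1 or 2.
#' @return The protein sequence as a character string.
#' @examples
#' translate_dna("ATGAAA") # "MK"
#' @export
translate_dna <- function(seq, frame = 0L) {
  assert_dna(seq)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  body <- substr(seq, frame + 1L, nchar(seq))
  n_codon <- nchar(body) %/% 3L
  if (n_codon < 1L) stop("sequence too short to contain a codon in this frame",
                         call. = FALSE)
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(body, starts, starts + 2L)
  paste0(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# deterministic pseudo-random DNA with a private RNG stream
random_dna <- function(n, seed = NULL) {
  draw <- function() paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  if (is.null(seed)) return(draw())
  with_private_seed(seed, draw())
}

# Run code under a temporary RNG state derived from `seed`, restoring the
# caller's RNG stream afterwards. Keeps builders deterministic without
# clobbering user-level set.seed().
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# small stable hash for deterministic per-name seeds
name_seed <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Replace occurrences of any motif in `motifs` (searched on both strands)
# inside `seq` by mutating one base per occurrence until clean. Used by the
# fixture/backbone generators to produce filler free of recognition sites.
scrub_motifs <- function(seq, motifs, circular = FALSE, max_iter = 200L) {
  both <- unique(c(motifs, vapply(motifs, rc, character(1))))
  chars <- strsplit(seq, "")[[1]]
  for (iter in seq_len(max_iter)) {
    cur <- paste0(chars, collapse = "")
    hit_any <- FALSE
    for (m in both) {
      starts <- scan_string(cur, m, circular = circular)
      if (length(starts)) {
        hit_any <- TRUE
        L <- length(chars)
        for (s in starts) {
          # flip the middle base of the occurrence to break the motif
          pos <- (s + nchar(m) %/% 2L) %% L + 1L
          chars[pos] <- switch(chars[pos],
                               A = "C", C = "A", G = "T", T = "G")
        }
        cur <- paste0(chars, collapse = "")
      }
    }
    if (!hit_any) return(cur)
  }
  stop("scrub_motifs failed to converge", call. = FALSE)
}
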