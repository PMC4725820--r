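# Digestion products: duplex fragments with 0- or 3-nt 5' single-stranded
# extensions. The `top` slot holds left_ov + core (the full top strand); the
# bottom strand runs from the end of the left overhang to 3 nt past the top
# strand when a right overhang is present.
#
# Mark and feature coordinates on a fragment live in a frame whose origin is
# the first base of the left overhang; top-strand positions are valid in
# [0, nchar(top)), bottom-strand positions in [3, nchar(top) + 3) when both
# overhangs are 3 nt.

new_fragment <- function(core, left_ov = "", right_ov = "", circular = FALSE,
                         marks = empty_marks(), features = empty_features(),
                         provenance = NULL) {
  stopifnot(nchar(left_ov) %in% c(0L, 3L), nchar(right_ov) %in% c(0L, 3L))
  if (is.null(provenance)) {
    provenance <- quick_tbl(parent = character(),
                            parent_start = integer(),
                            parent_end = integer())
  }
  structure(
    list(core = core, left_ov = left_ov, right_ov = right_ov,
         circular = circular, marks = marks, features = features,
         provenance = provenance),
    class = "tnt_fragment")
}

fragment_top <- function(f) paste0(f$left_ov, f$core)

# fragment size as reported on a gel and as it partitions the parent:
# the cut-to-cut span (junction 3-mers are counted with the fragment whose
# top strand carries them, so sizes sum exactly to the parent length)
fragment_size <- function(f) {
  nchar(f$left_ov) + nchar(f$core)
}

# full footprint including the 3-nt right single-stranded extension
fragment_span <- function(f) {
  nchar(f$left_ov) + nchar(f$core) + nchar(f$right_ov)
}

# top-strand length (used for product concatenation: junction 3-mers are
# counted once because the next fragment's left overhang supplies them)
fragment_toplen <- function(f) nchar(f$left_ov) + nchar(f$core)

#' @export
print.tnt_fragment <- function(x, ...) {
  cat(sprintf("<tnt_fragment> %s[%s...%s] %d bp%s\n",
              if (x$circular) "circular " else "",
              x$left_ov, x$right_ov, fragment_size(x),
              if (nrow(x$provenance))
                paste0(" from ", paste(unique(x$provenance$parent),
                                       collapse = "+")) else ""))
  invisible(x)
}

# Reverse complement a fragment: ends swap, single-stranded extensions stay
# 5' extensions, marks/features reflect through the full footprint.
flip_fragment <- function(f) {
  if (f$circular) stop("cannot flip a circular fragment this way",
                       call. = FALSE)
  W <- fragment_toplen(f) + nchar(f$right_ov)
  out <- f
  out$left_ov <- f$right_ov
  out$right_ov <- f$left_ov
  # new core spans [len(new left_ov), W - len(new right_ov)) of the flipped
  # footprint; equivalently rc of old footprint's same region
  footprint_top <- paste0(fragment_top(f), rc_or_empty(f$right_ov))
  # top strand of the flipped footprint is rc of the bottom strand read
  # 5'->3'; bases single-stranded on the old top become single-stranded on
  # the new bottom. Sequence-wise the flipped footprint top strand is
  # rc(old footprint top) because the footprint is written as top-strand
  # coordinates.
  flipped <- rc(footprint_top)
  out$core <- substr(flipped, nchar(out$left_ov) + 1L, W - nchar(out$right_ov))
  if (nrow(f$marks)) {
    out$marks <- f$marks
    out$marks$position <- W - 1L - f$marks$position
    out$marks$strand <- ifelse(f$marks$strand == "top", "bottom", "top")
  }
  if (nrow(f$features)) {
    out$features <- f$features
    out$features$start <- W - f$features$end
    out$features$end <- W - f$features$start
    out$features$strand <- ifelse(f$features$strand == "+", "-", "+")
  }
  out
}

rc_or_empty <- function(x) if (nchar(x)) rc(x) else ""

# The 3-mer a joining partner's left overhang must equal: the junction's
# top-strand sequence, i.e. the Watson-Crick complement of this fragment's
# right (bottom-strand) overhang.
right_junction_top <- function(f) rc_or_empty(f$right_ov)
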