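# The 17-member vector registry (1 entry + 8 alpha + 8 omega) and the
# synthesis of annotated member plasmids for simulation.
#
# Member geometry (all cuts produce the junction 3-mer as the downstream
# fragment's top-strand 5' extension):
#
#   entry (pSTART):   ...GCTCTTC C [J1  insert  J2top] G GAAGAGC...
#     dual-purpose flanks: EarI and LguI cut at the same coordinates,
#     exposing s1 on the left and s2 on the right of the insert.
#   alpha members:    accept with EarI, release with LguI through
#     M.TaqI-protected composite sites (GCTCTTCG A.. -> TCGA overlap):
#     ...GCTCTTC G [relL] | [accL] G GAAGAG T ..stuffer.. CTCTTC C | [accR] [relR] C GAAGAGC...
#   omega members:    accept with LguI (sites inside the stuffer), release
#     with EarI through unprotected ccCTCTTC sites:
#     ...CC CTCTTC C [relL] | [accL] G GAAGAGC ..stuffer.. GCTCTTC C | [accR] [relR] G GAAGAG GG...
#
# "|" marks the accept cuts; bracketed 3-mers are signature junctions. When
# a release junction coincides with the accept junction (variant 1A left,
# variants 2/C right) the two cuts share one coordinate.

VARIANT_RELEASE <- list(
  "1A" = c("s1", "s3"),
  "2"  = c("s3", "s2"),
  "B"  = c("s3", "s4"),
  "C"  = c("s4", "s2"))

#' Build the vector registry
#'
#' Returns the 17 members of the platform: the entry vector pSTART
#' (carbenicillin resistance), eight alpha members (spectinomycin) and
#' eight omega members (kanamycin), in deterministic order. Alpha members
#' receive inserts with EarI and release with LguI; omega members the
#' opposite; pSTART does both with either enzyme. Release flanks follow the
#' variant: 1A (s1,s3), 2 (s3,s2), B (s3,s4), C (s4,s2); R variants share
#' the flanks of their sense counterpart but store and release the insert
#' in antisense orientation.
#'
#' @param sigs A `tnt_signature_set` (defaults to [signature_set()]).
#' @return Tibble with one row per member and attribute `"signatures"`.
#' @export
build_registry <- function(sigs = signature_set()) {
  if (!inherits(sigs, "tnt_signature_set")) {
    sigs <- do.call(signature_set, as.list(sigs))
  }
  variants <- c("1A", "2", "B", "C")
  rows <- list(tibble::tibble(
    name = "pSTART", family = "entry", variant = "START",
    resistance = "carbenicillin",
    accept_enzyme = "EarI+LguI", release_enzyme = "EarI+LguI",
    accept_left = "s1", accept_right = "s2",
    release_left = "s1", release_right = "s2",
    release_orientation = "sense",
    requires_methylated_propagation = FALSE,
    release_site_upstream_context = ""))
  for (fam in c("alpha", "omega")) {
    for (rev_variant in c(FALSE, TRUE)) {
      for (v in variants) {
        fl <- VARIANT_RELEASE[[v]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          name = paste0(fam, v, if (rev_variant) "-R" else ""),
          family = fam,
          variant = paste0(v, if (rev_variant) "-R" else ""),
          resistance = if (fam == "alpha") "spectinomycin" else "kanamycin",
          accept_enzyme = if (fam == "alpha") "EarI" else "LguI",
          release_enzyme = if (fam == "alpha") "LguI" else "EarI",
          accept_left = if (rev_variant) "s1R" else "s1",
          accept_right = if (rev_variant) "s2R" else "s2",
          release_left = fl[1], release_right = fl[2],
          release_orientation = if (rev_variant) "antisense" else "sense",
          requires_methylated_propagation = fam == "alpha",
          release_site_upstream_context = if (fam == "omega") "cc" else "")
      }
    }
  }
  # order: entry, alpha sense, alpha R, omega sense, omega R
  reg <- dplyr::bind_rows(rows)
  ord <- c(1L, 2:5, 6:9, 10:13, 14:17)
  reg <- reg[order(match(reg$family, c("entry", "alpha", "omega")),
                   grepl("-R$", reg$variant),
                   match(sub("-R$", "", reg$variant),
                         c("START", variants))), ]
  attr(reg, "signatures") <- sigs
  reg
}

registry_member <- function(registry, name) {
  hit <- registry[registry$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) stop("unknown registry member: ", name, call. = FALSE)
  as.list(hit)
}

# -- member plasmid synthesis ------------------------------------------------

default_stuffer_seq <- function(n = 210L) {
  # lacZ-like reporter placeholder (white/blue screening stand-in)
  filler <- random_dna(n, seed = name_seed("lacZ-alpha-stuffer"))
  scrub_motifs(filler, c("CTCTTC", "GAAGAG", "GAGCTC", "TCGA"))
}

#' Synthesise a member plasmid
#'
#' Builds a circular, annotated plasmid for a registry member: two
#' accept-enzyme sites cut outward-facing overhangs equal to the accept
#' flanks while excising themselves with the stuffer; two release-enzyme
#' sites flank the cloning region exposing the release flanks. For alpha
#' members the release sites are TCGA-composite contexts and M.TaqI marks
#' are applied (the state after propagation in the methyltransferase-
#' expressing host); omega release sites carry the upstream `cc` context.
#'
#' @param member A member name or one-row registry subset.
#' @param registry Registry tibble from [build_registry()].
#' @param stuffer Optional `tnt_dna` (an element to pre-load) or character
#'   sequence placed between the accept junctions; default is a reporter
#'   placeholder. Internal unprotected recognition sites are an error.
#' @param backbone_length Length of the synthetic backbone filler (bp).
#' @return A circular `tnt_dna` plasmid.
#' @export
make_member_plasmid <- function(member, registry = build_registry(),
                                stuffer = NULL, backbone_length = 1200L) {
  if (is.character(member)) member <- registry_member(registry, member)
  if (inherits(member, "tbl_df")) member <- as.list(member)
  sigs <- attr(registry, "signatures")
  J <- junction_tops(sigs)
  JR <- r_accept_junctions(sigs)
  fam <- member$family
  is_r <- member$release_orientation == "antisense"
  if (fam == "entry") {
    acc <- c(left = unname(J["s1"]), right = unname(J["s2"]))
  } else if (is_r) {
    acc <- c(left = unname(JR["left"]), right = unname(JR["right"]))
  } else {
    acc <- c(left = unname(J["s1"]), right = unname(J["s2"]))
  }
  rel <- c(left = unname(J[[member$release_left]]),
           right = unname(J[[member$release_right]]))

  stuffer_label <- "stuffer"
  stuffer_type <- "stuffer"
  stuffer_strand <- "+"
  if (inherits(stuffer, "tnt_dna")) {
    stuffer_label <- stuffer$id
    stuffer_type <- "element"
    stuffer_seq <- stuffer$sequence
    if (is_r) {
      stuffer_seq <- rc(stuffer_seq)
      stuffer_strand <- "-"
    }
  } else if (is.character(stuffer)) {
    stuffer_seq <- toupper(stuffer)
  } else {
    stuffer_seq <- default_stuffer_seq()
  }
  if (length(scan_string(stuffer_seq, "CTCTTC")) ||
      length(scan_string(stuffer_seq, "GAAGAG"))) {
    stop("stuffer/element contains an internal unprotected recognition site; ",
         "domesticate it or use the BlindSpot route", call. = FALSE)
  }

  for (try_seed in 0:24) {
    bb <- random_dna(backbone_length,
                     seed = name_seed(paste0(member$name, "#", try_seed)))
    bb <- scrub_motifs(bb, c("CTCTTC", "GAAGAG", "GAGCTC", "TCGA"))
    mol <- assemble_member(member, fam, acc, rel, stuffer_seq,
                           stuffer_label, stuffer_type, stuffer_strand,
                           bb, sigs)
    if (member_sites_ok(mol, fam, stuffer_type)) {
      if (isTRUE(member$requires_methylated_propagation)) {
        mol <- apply_methyltransferase(mol, "M.TaqI")
      }
      return(mol)
    }
    if (stuffer_type == "element") {
      stop("element boundary creates an unintended recognition site in ",
           member$name, "; adjust the element ends", call. = FALSE)
    }
  }
  stop("could not assemble a clean backbone for ", member$name,
       call. = FALSE)
}

assemble_member <- function(member, fam, acc, rel, stuffer_seq,
                            stuffer_label, stuffer_type, stuffer_strand,
                            bb, sigs) {
  pieces <- character()
  feats <- list()
  cursor <- 0L
  add <- function(seq, label = NULL, type = NULL, strand = "+") {
    pieces[[length(pieces) + 1L]] <<- seq
    if (!is.null(label)) {
      feats[[length(feats) + 1L]] <<- tibble::tibble(
        label = label, start = cursor, end = cursor + nchar(seq),
        strand = strand, type = type)
    }
    cursor <<- cursor + nchar(seq)
  }

  sig_label <- function(side) {
    if (fam == "entry") return(if (side == "left") "s1" else "s2")
    if (member$release_orientation == "antisense") {
      return(if (side == "left") member$accept_left else member$accept_right)
    }
    if (side == "left") "s1" else "s2"
  }

  if (fam == "entry") {
    add("GCTCTTCC", label = "EarI/LguI flank L", type = "entry_flank")
    add(acc[["left"]], label = "s1", type = "signature")
    add(stuffer_seq, label = stuffer_label, type = stuffer_type,
        strand = stuffer_strand)
    add(acc[["right"]], label = "s2", type = "signature")
    add("GGAAGAGC", label = "EarI/LguI flank R", type = "entry_flank")
  } else if (fam == "alpha") {
    add("GCTCTTCG", label = "LguI composite L (M.TaqI-protected)",
        type = "site")
    if (rel[["left"]] != acc[["left"]]) {
      add(rel[["left"]], label = member$release_left, type = "signature")
    }
    add(acc[["left"]], label = sig_label("left"), type = "signature")
    add("GGAAGAGT", label = "EarI accept L", type = "site")
    add(stuffer_seq, label = stuffer_label, type = stuffer_type,
        strand = stuffer_strand)
    add("CTCTTCC", label = "EarI accept R", type = "site")
    add(acc[["right"]], label = sig_label("right"), type = "signature")
    if (rel[["right"]] != acc[["right"]]) {
      add(rel[["right"]], label = member$release_right, type = "signature")
    }
    add("CGAAGAGC", label = "LguI composite R (M.TaqI-protected)",
        type = "site")
  } else { # omega
    add("CCCTCTTCC", label = "EarI release L (cc context)", type = "site")
    if (rel[["left"]] != acc[["left"]]) {
      add(rel[["left"]], label = member$release_left, type = "signature")
    }
    add(acc[["left"]], label = sig_label("left"), type = "signature")
    add("GGAAGAGC", label = "LguI accept L", type = "site")
    add(stuffer_seq, label = stuffer_label, type = stuffer_type,
        strand = stuffer_strand)
    add("GCTCTTCC", label = "LguI accept R", type = "site")
    add(acc[["right"]], label = sig_label("right"), type = "signature")
    if (rel[["right"]] != acc[["right"]]) {
      add(rel[["right"]], label = member$release_right, type = "signature")
    }
    add("GGAAGAGGG", label = "EarI release R (cc context)", type = "site")
  }
  add(bb, label = member$name, type = "backbone")
  dna_molecule(member$name, paste0(pieces, collapse = ""), "circular",
               features = dplyr::bind_rows(feats))
}

member_sites_ok <- function(mol, fam, stuffer_type) {
  n_ear <- nrow(find_motifs(mol, "CTCTTC", "top")) +
    nrow(find_motifs(mol, "GAAGAG", "top"))
  n_lgu <- nrow(find_motifs(mol, "GCTCTTC", "top")) +
    nrow(find_motifs(mol, "GAAGAGC", "top"))
  if (fam == "entry") return(n_ear == 2L && n_lgu == 2L)
  if (fam == "alpha") return(n_ear == 4L && n_lgu == 2L)
  n_ear == 4L && n_lgu == 2L # omega: 2 release + 2 nested in accept sites
}

#' Build an entry clone
#'
#' Places an element in the entry vector (pSTART), flanked by signatures 1
#' and 2.
#'
#' @param element A `tnt_dna` molecule (linear element, top strand = sense).
#' @param registry Registry tibble.
#' @param backbone_length Backbone filler length.
#' @return Circular `tnt_dna` entry clone named `pSTART:<element id>`.
#' @export
make_entry_clone <- function(element, registry = build_registry(),
                             backbone_length = 300L) {
  el <- element
  if (!nrow(el$features) || !any(el$features$type == "element")) {
    el$features <- dplyr::bind_rows(
      el$features,
      tibble::tibble(label = el$id, start = 0L, end = dna_length(el),
                     strand = "+", type = "element"))
  }
  mol <- make_member_plasmid("pSTART", registry, stuffer = el,
                             backbone_length = backbone_length)
  mol$id <- paste0("pSTART:", element$id)
  mol
}
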