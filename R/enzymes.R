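# Type IIS enzymes (EarI/LguI class: 3-nt 5' overhangs cut downstream of the
# recognition site) and methyltransferases, with methylation-blocked site
# listing and deterministic / stochastic digestion.

#' Define a type IIS restriction enzyme
#'
#' The enzyme cuts downstream of its recognition site, nicking the top
#' strand `cut_top_offset` nt after the 3' end of the recognition sequence
#' and the bottom strand 3 nt further, leaving 3-nt 5' overhangs.
#'
#' @param name Enzyme name.
#' @param recognition Top-strand recognition motif.
#' @param cut_top_offset Distance from recognition 3' end to the top nick.
#' @param blocking_rules List of blocking rules (see
#'   [blocking_rule()]).
#' @param promiscuity_context Optional upstream dinucleotide that triggers
#'   an off-target (star-activity) warning, e.g. `"aa"` for LguI over the
#'   aaCTCTTC context.
#' @param aliases Character vector of isoschizomer names.
#' @return A `tnt_enzyme` object.
#' @export
type_iis_enzyme <- function(name, recognition, cut_top_offset = 1L,
                            blocking_rules = list(),
                            promiscuity_context = NULL,
                            aliases = character()) {
  structure(
    list(name = name, recognition = toupper(recognition),
         cut_top_offset = as.integer(cut_top_offset),
         cut_bottom_offset = as.integer(cut_top_offset) + 3L,
         blocking_rules = blocking_rules,
         promiscuity_context = promiscuity_context,
         aliases = aliases),
    class = "tnt_enzyme")
}

#' Define a methylation blocking rule
#'
#' A rule names the methylation marks that protect a recognition site from
#' cleavage. Offsets are relative to the recognition-site start on the
#' strand carrying the recognition sequence; `strand` is relative to that
#' same strand. A site counts as protected when any of the listed marks is
#' present (hemimethylated duplexes remain blocked), with the given
#' efficiency (fraction of cleavage inhibited, in \[0, 1\]).
#'
#' @param source Methyltransferase name the rule corresponds to.
#' @param kind Mark kind, `"m6A"` or `"m5C"`.
#' @param offsets Tibble with columns `strand` and `offset`.
#' @param efficiency Fraction in \[0,1\] by which cleavage is inhibited.
#' @return A `tnt_blocking_rule` object.
#' @export
blocking_rule <- function(source, kind, offsets, efficiency) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  structure(list(source = source, kind = kind,
                 offsets = tibble::as_tibble(offsets),
                 efficiency = efficiency),
            class = "tnt_blocking_rule")
}

#' Define a methyltransferase
#'
#' @param name Methyltransferase name.
#' @param recognition Recognition motif (top strand).
#' @param kind Mark deposited: `"m6A"` or `"m5C"`.
#' @param top_offsets Integer offsets (0-based, within the motif as read on
#'   the strand carrying it) of modified bases on that strand.
#' @param bottom_offsets Offsets, in the same top-coordinate frame of the
#'   motif occurrence, of modified bases on the opposite strand.
#' @return A `tnt_mtase` object.
#' @export
methyltransferase <- function(name, recognition, kind,
                              top_offsets, bottom_offsets) {
  structure(list(name = name, recognition = toupper(recognition),
                 kind = kind, top_offsets = as.integer(top_offsets),
                 bottom_offsets = as.integer(bottom_offsets)),
            class = "tnt_mtase")
}

# -- built-in definitions ----------------------------------------------------

# M.TaqI protection of the composite ...CTCTTCGA... context: the TCGA motif
# overlaps the recognition site so that the methylated adenines sit at
# top +7 / bottom +4 relative to the CTCTTC start (one more for GCTCTTC).
taqi_rule <- function(rec_len, efficiency = 1.0) {
  d <- rec_len - 6L
  blocking_rule("M.TaqI", "m6A",
                tibble::tibble(strand = c("top", "bottom"),
                               offset = c(7L + d, 4L + d)),
                efficiency)
}

# M.SacI methylation of a GAGCTC overlapping the site (composite GAGCTCTTC)
# leaves a 5mC inside the recognition sequence; partial inhibition.
saci_rule <- function(rec_len, efficiency = 0.834) {
  d <- rec_len - 6L
  blocking_rule("M.SacI", "m5C",
                tibble::tibble(strand = c("top", "bottom"),
                               offset = c(2L + d, -3L + d)),
                efficiency)
}

# M.SssI (CpG) marks have little to no effect on EarI; efficiency 0 keeps
# the rule visible but never blocking.
sssi_rule <- function(rec_len, efficiency = 0.0) {
  d <- rec_len - 6L
  blocking_rule("M.SssI", "m5C",
                tibble::tibble(strand = c("top", "bottom"),
                               offset = c(0L + d, 1L + d)),
                efficiency)
}

#' Built-in enzyme definitions
#'
#' `tnt_enzyme("EarI")` and `tnt_enzyme("LguI")` return the two enzymes of
#' the platform: EarI recognises CTCTTC (nested inside the LguI site
#' GCTCTTC); both cut 1 nt downstream on the top strand and 4 nt on the
#' bottom strand, leaving 3-nt 5' overhangs. Aliases (Eam1104I for EarI;
#' SapI/BspQI for LguI) are accepted.
#'
#' @param name Enzyme (or alias) name.
#' @return A `tnt_enzyme` object.
#' @export
tnt_enzyme <- function(name) {
  key <- toupper(name)
  if (key %in% c("EARI", "EAM1104I")) {
    type_iis_enzyme("EarI", "CTCTTC",
                    blocking_rules = list(taqi_rule(6L), saci_rule(6L),
                                          sssi_rule(6L)),
                    aliases = "Eam1104I")
  } else if (key %in% c("LGUI", "SAPI", "BSPQI")) {
    type_iis_enzyme("LguI", "GCTCTTC",
                    blocking_rules = list(taqi_rule(7L), saci_rule(7L),
                                          sssi_rule(7L)),
                    promiscuity_context = "AA",
                    aliases = c("SapI", "BspQI"))
  } else {
    stop("unknown enzyme: ", name, call. = FALSE)
  }
}

#' Built-in methyltransferase definitions
#'
#' M.TaqI (TCGA, m6A on both adenines), M.SacI (GAGCTC, m5C) and M.SssI
#' (CG, m5C on both cytosines). All three motifs are palindromic, so one
#' physical site carries one mark per strand.
#'
#' @param name Methyltransferase name (`"M.TaqI"`, `"M.SacI"`, `"M.SssI"`).
#' @return A `tnt_mtase` object.
#' @export
tnt_methyltransferase <- function(name) {
  key <- toupper(name)
  if (key == "M.TAQI") {
    methyltransferase("M.TaqI", "TCGA", "m6A", top_offsets = 3L,
                      bottom_offsets = 0L)
  } else if (key == "M.SACI") {
    methyltransferase("M.SacI", "GAGCTC", "m5C", top_offsets = 5L,
                      bottom_offsets = 0L)
  } else if (key == "M.SSSI") {
    methyltransferase("M.SssI", "CG", "m5C", top_offsets = 0L,
                      bottom_offsets = 1L)
  } else {
    stop("unknown methyltransferase: ", name, call. = FALSE)
  }
}

# -- methylation -------------------------------------------------------------

#' Apply a methyltransferase to a molecule
#'
#' Adds marks at every motif occurrence on both strands; idempotent.
#'
#' @param mol A `tnt_dna` molecule.
#' @param mtase A `tnt_mtase` (or its name).
#' @return A copy of the molecule with marks added.
#' @export
apply_methyltransferase <- function(mol, mtase) {
  if (is.character(mtase)) mtase <- tnt_methyltransferase(mtase)
  L <- dna_length(mol)
  m <- nchar(mtase$recognition)
  hits <- find_motifs(mol, mtase$recognition, "both")
  if (!nrow(hits)) return(mol)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]
    if (hits$strand[i] == "top") {
      pos <- c(s + mtase$top_offsets, s + mtase$bottom_offsets)
      strand <- rep(c("top", "bottom"),
                    c(length(mtase$top_offsets),
                      length(mtase$bottom_offsets)))
    } else {
      # motif on the bottom strand: its own-strand offsets count from the
      # rightmost top coordinate leftwards, strands swap
      pos <- c(s + m - 1L - mtase$top_offsets, s + m - 1L - mtase$bottom_offsets)
      strand <- rep(c("bottom", "top"),
                    c(length(mtase$top_offsets),
                      length(mtase$bottom_offsets)))
    }
    rows[[i]] <- quick_tbl(position = as.integer(pos %% L),
                           strand = strand,
                           kind = rep(mtase$kind, length(pos)),
                           source = rep(mtase$name, length(pos)))
  }
  new_marks <- dplyr::distinct(quick_bind(c(list(mol$marks), rows)))
  mol$marks <- new_marks
  validate_molecule(mol)
}

# -- cut-site listing --------------------------------------------------------

mark_present <- function(marks, position, strand, kind, L, circular) {
  if (!nrow(marks)) return(FALSE)
  p <- if (circular) position %% L else position
  any(marks$position == p & marks$strand == strand & marks$kind == kind)
}

#' List cut sites of a type IIS enzyme on a molecule
#'
#' Reports every recognition occurrence on both strands with its cut
#' coordinates (`cut_top` is the 0-based top-strand position immediately
#' right of the top nick; `cut_bottom = cut_top + 3`, so the 3-nt 5'
#' overhang is the top strand over `[cut_top, cut_bottom)`), whether the
#' site is blocked by methylation marks, and a status flag: `"ok"`,
#' `"uncuttable_terminal"` (linear molecule, cut falls off the end). Sites
#' matching the enzyme's promiscuity context gain a `warn_promiscuity`
#' flag.
#'
#' @param mol A `tnt_dna` molecule.
#' @param enzyme A `tnt_enzyme` (or its name).
#' @return Tibble with one row per site.
#' @export
list_cut_sites <- function(mol, enzyme) {
  if (is.character(enzyme)) enzyme <- tnt_enzyme(enzyme)
  L <- dna_length(mol)
  circ <- is_circular(mol)
  m <- nchar(enzyme$recognition)
  hits <- find_motifs(mol, enzyme$recognition, "both")
  n <- nrow(hits)
  col_strand <- character(n); col_rec <- integer(n)
  col_ct <- integer(n); col_cb <- integer(n)
  col_eff <- numeric(n); col_status <- character(n)
  col_warn <- logical(n)
  if (!n) {
    return(quick_tbl(enzyme = character(), strand = character(),
                     rec_start = integer(), cut_top = integer(),
                     cut_bottom = integer(), blocked = logical(),
                     efficiency = numeric(), status = character(),
                     warn_promiscuity = logical()))
  }
  for (i in seq_len(n)) {
    s <- hits$start[i]
    str <- hits$strand[i]
    if (str == "top") {
      ct <- s + m + enzyme$cut_top_offset
    } else {
      ct <- s - enzyme$cut_top_offset - 3L
    }
    cb <- ct + 3L
    status <- "ok"
    if (!circ && (ct < 0L || cb > L)) status <- "uncuttable_terminal"
    if (circ) { ct <- ct %% L; cb <- ct + 3L }
    eff <- 0
    for (rule in enzyme$blocking_rules) {
      hit_rule <- FALSE
      for (j in seq_len(nrow(rule$offsets))) {
        o <- rule$offsets$offset[j]
        rel_strand <- rule$offsets$strand[j]
        if (str == "top") {
          pos <- s + o
          phys_strand <- rel_strand
        } else {
          pos <- s + m - 1L - o
          phys_strand <- if (rel_strand == "top") "bottom" else "top"
        }
        if (!circ && (pos < 0L || pos >= L)) next
        if (mark_present(mol$marks, pos, phys_strand, rule$kind, L, circ)) {
          hit_rule <- TRUE
          break
        }
      }
      if (hit_rule) eff <- max(eff, rule$efficiency)
    }
    warn <- FALSE
    if (!is.null(enzyme$promiscuity_context)) {
      ctx_len <- nchar(enzyme$promiscuity_context)
      ctx <- if (str == "top") {
        extract_span(mol$sequence, s - ctx_len, s, circ)
      } else {
        rc_or_empty(extract_span(mol$sequence, s + m, s + m + ctx_len, circ))
      }
      warn <- identical(toupper(ctx), toupper(enzyme$promiscuity_context))
    }
    col_strand[i] <- str
    col_rec[i] <- s
    col_ct[i] <- ct
    col_cb[i] <- cb
    col_eff[i] <- eff
    col_status[i] <- status
    col_warn[i] <- warn
  }
  ord <- order(col_ct, col_strand)
  quick_tbl(enzyme = rep(enzyme$name, n), strand = col_strand[ord],
            rec_start = col_rec[ord], cut_top = col_ct[ord],
            cut_bottom = col_cb[ord], blocked = col_eff[ord] >= 0.5,
            efficiency = col_eff[ord], status = col_status[ord],
            warn_promiscuity = col_warn[ord])
}

# substring with circular wraparound; returns "" when the span runs off a
# linear molecule
extract_span <- function(seq, from, to, circular) {
  L <- nchar(seq)
  if (!circular) {
    if (from < 0L || to > L) return("")
    return(substr(seq, from + 1L, to))
  }
  idx <- (seq.int(from, to - 1L) %% L) + 1L
  paste0(substring(seq, idx, idx), collapse = "")
}

# -- digestion ---------------------------------------------------------------

#' Digest a molecule with a type IIS enzyme
#'
#' Cuts at every unblocked site (full-digestion idealisation). A circular
#' molecule with k unblocked sites yields k fragments; a linear molecule
#' yields k + 1. Fragments carry 3-nt 5' overhangs, inherit methylation
#' marks and features remapped to fragment coordinates, and record their
#' provenance. A molecule without cuttable sites is returned as a single
#' uncut (circular or blunt linear) fragment.
#'
#' @param mol A `tnt_dna` molecule.
#' @param enzyme A `tnt_enzyme` (or its name).
#' @return List of `tnt_fragment` objects with attribute `"sites"` (the
#'   cut-site table).
#' @export
digest <- function(mol, enzyme) {
  if (is.character(enzyme)) enzyme <- tnt_enzyme(enzyme)
  sites <- list_cut_sites(mol, enzyme)
  active <- sites[!sites$blocked & sites$status == "ok", , drop = FALSE]
  cuts <- sort(unique(active$cut_top))
  L <- dna_length(mol)
  check_cut_conflicts(cuts, L, is_circular(mol))
  frags <- cut_molecule(mol, cuts)
  attr(frags, "sites") <- sites
  class(frags) <- c("tnt_digest", "list")
  frags
}

#' @export
print.tnt_digest <- function(x, ...) {
  cat(sprintf("<tnt_digest> %d fragment(s): %s bp\n", length(x),
              paste(sort(vapply(x, fragment_size, integer(1)),
                         decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.tnt_digest <- function(x, ...) tidy_digest(x)

#' Plot a digestion as a gel-like lane
#'
#' Fragment sizes on a log scale, one horizontal band per fragment, the
#' way the digest would appear on an agarose gel.
#'
#' @param object A `tnt_digest` (result of [digest()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnt_digest <- function(object, ...) {
  td <- tidy_digest(object)
  ggplot2::ggplot(td, ggplot2::aes(x = 1, y = .data$size)) +
    ggplot2::geom_tile(width = 0.6, height = 0.015 * td$size,
                       fill = "grey20") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_continuous(breaks = NULL, limits = c(0.5, 1.5)) +
    ggplot2::labs(x = NULL, y = "fragment size (bp)") +
    ggplot2::theme_minimal()
}

check_cut_conflicts <- function(cuts, L, circular) {
  if (length(cuts) < 2L) return(invisible())
  gaps <- diff(cuts)
  if (circular) gaps <- c(gaps, L - cuts[length(cuts)] + cuts[1])
  bad <- which(gaps < 3L)
  if (length(bad)) {
    stop(sprintf("conflicting-cuts: cut positions %d and %d overlap (< 3 nt apart)",
                 cuts[bad[1]], cuts[(bad[1] %% length(cuts)) + 1L]),
         call. = FALSE)
  }
  invisible()
}

# Split a molecule at the given top-nick coordinates into fragments.
cut_molecule <- function(mol, cuts) {
  L <- dna_length(mol)
  if (!length(cuts)) {
    f <- new_fragment(mol$sequence, circular = is_circular(mol),
                      marks = mol$marks, features = mol$features,
                      provenance = quick_tbl(parent = mol$id,
                                             parent_start = 0L,
                                             parent_end = L))
    return(list(f))
  }
  if (is_circular(mol)) {
    mol <- rotate_molecule(mol, cuts[1])
    cuts <- sort((cuts - cuts[1]) %% L)
    bounds <- cbind(cuts, c(cuts[-1], L))
  } else {
    bounds <- cbind(c(0L, cuts), c(cuts, L))
  }
  seq2 <- paste0(mol$sequence, substr(mol$sequence, 1L, 3L)) # wrap for ov
  lapply(seq_len(nrow(bounds)), function(i) {
    a <- bounds[i, 1]; b <- bounds[i, 2]
    if (is_circular(mol)) {
      has_left <- TRUE
      has_right <- TRUE
    } else {
      has_left <- a != 0L
      has_right <- b != L
    }
    top <- substr(mol$sequence, a + 1L, b)
    left_ov <- if (has_left) substr(top, 1L, 3L) else ""
    core <- if (has_left) substr(top, 4L, nchar(top)) else top
    right_ov <- if (has_right) rc(substr(seq2, b + 1L, b + 3L)) else ""
    keep_marks <- mol$marks[
      (mol$marks$strand == "top" &
         mol$marks$position >= a & mol$marks$position < b) |
        (mol$marks$strand == "bottom" &
           mol$marks$position >= a + ifelse(has_left, 3L, 0L) &
           mol$marks$position < b + ifelse(has_right, 3L, 0L)), ,
      drop = FALSE]
    if (nrow(keep_marks)) keep_marks$position <- keep_marks$position - a
    keep_feats <- mol$features[
      mol$features$start >= a & mol$features$end <= b + 3L, , drop = FALSE]
    if (nrow(keep_feats)) {
      keep_feats$start <- keep_feats$start - a
      keep_feats$end <- keep_feats$end - a
    }
    new_fragment(core, left_ov, right_ov, circular = FALSE,
                 marks = keep_marks, features = keep_feats,
                 provenance = quick_tbl(parent = mol$id,
                                        parent_start = a,
                                        parent_end = b))
  })
}

#' Tidy a digestion result
#'
#' @param x Result of [digest()].
#' @param ... Unused.
#' @return Tibble of fragment sizes and overhangs.
#' @export
tidy_digest <- function(x, ...) {
  tibble::tibble(
    fragment = seq_along(x),
    size = vapply(x, fragment_size, integer(1)),
    circular = vapply(x, function(f) f$circular, logical(1)),
    left_overhang = vapply(x, function(f) f$left_ov, character(1)),
    right_overhang = vapply(x, function(f) f$right_ov, character(1)),
    parent = vapply(x, function(f)
      paste(unique(f$provenance$parent), collapse = "+"), character(1)))
}

# -- stochastic (partial) digestion -----------------------------------------

#' Simulate partial digestion of a pool of molecules
#'
#' Each of `n_molecules` copies of each pool member cuts each cuttable site
#' independently with the given per-site probability; unspecified sites cut
#' with probability 1 (full digestion). Site keys are top-nick coordinates
#' (`cut_top`), as character names of `per_site_probability`.
#'
#' @param pool A `tnt_dna` molecule or list of molecules.
#' @param enzyme A `tnt_enzyme` (or name).
#' @param per_site_probability Named numeric vector, names = `cut_top`
#'   coordinates, values in \[0,1\].
#' @param n_molecules Number of molecules to simulate per pool member.
#' @param seed Integer seed for reproducibility.
#' @return List with `site_summary` (tibble: molecule, cut_top, probability,
#'   cut_fraction) and `fragment_population` (tibble: molecule, size, count).
#' @export
digest_partial <- function(pool, enzyme, per_site_probability = numeric(),
                           n_molecules = 1000L, seed = 1L) {
  if (inherits(pool, "tnt_dna")) pool <- list(pool)
  if (is.character(enzyme)) enzyme <- tnt_enzyme(enzyme)
  stopifnot(n_molecules >= 1L)
  if (length(per_site_probability) &&
      (any(per_site_probability < 0) || any(per_site_probability > 1))) {
    stop("per-site probabilities must lie in [0, 1]", call. = FALSE)
  }
  all_cuts <- lapply(pool, function(mol) {
    sites <- list_cut_sites(mol, enzyme)
    sites <- sites[!sites$blocked & sites$status == "ok", , drop = FALSE]
    sort(unique(sites$cut_top))
  })
  known <- unlist(lapply(all_cuts, as.character))
  unknown <- setdiff(names(per_site_probability), known)
  if (length(unknown)) {
    stop("unknown site key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  summaries <- list()
  pops <- list()
  with_private_seed(seed, {
    for (mi in seq_along(pool)) {
      mol <- pool[[mi]]
      cuts <- all_cuts[[mi]]
      k <- length(cuts)
      probs <- rep(1, k)
      names(probs) <- as.character(cuts)
      hit <- intersect(names(per_site_probability), names(probs))
      probs[hit] <- per_site_probability[hit]
      if (k == 0L) {
        summaries[[mi]] <- tibble::tibble(molecule = mol$id,
                                          cut_top = integer(),
                                          probability = numeric(),
                                          cut_fraction = numeric())
        pops[[mi]] <- tibble::tibble(molecule = mol$id,
                                     size = dna_length(mol),
                                     count = n_molecules)
        next
      }
      draws <- matrix(stats::runif(n_molecules * k) < rep(probs,
                                                          each = n_molecules),
                      nrow = n_molecules)
      summaries[[mi]] <- tibble::tibble(
        molecule = mol$id, cut_top = cuts, probability = unname(probs),
        cut_fraction = colMeans(draws))
      # fragment populations by unique cut pattern
      code <- as.vector(draws %*% (2 ^ (seq_len(k) - 1L)))
      tab <- table(code)
      sizes_list <- lapply(as.integer(names(tab)), function(cd) {
        on <- cuts[bitwAnd(cd, 2 ^ (seq_len(k) - 1L)) > 0]
        pattern_sizes(dna_length(mol), on, is_circular(mol))
      })
      pop <- dplyr::bind_rows(lapply(seq_along(sizes_list), function(j) {
        tibble::tibble(size = sizes_list[[j]],
                       count = as.integer(tab[j]))
      }))
      pop <- dplyr::summarise(dplyr::group_by(pop, size),
                              count = sum(count), .groups = "drop")
      pop$molecule <- mol$id
      pops[[mi]] <- pop[, c("molecule", "size", "count")]
    }
  })
  list(site_summary = dplyr::bind_rows(summaries),
       fragment_population = dplyr::bind_rows(pops))
}

pattern_sizes <- function(L, cuts, circular) {
  if (!length(cuts)) return(L)
  cuts <- sort(cuts)
  if (circular) {
    diff(c(cuts, cuts[1] + L))
  } else {
    diff(c(0L, cuts, L))
  }
}
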