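# One-pot digestion-ligation simulation: overhang-compatibility graph over
# fragment ends, enumeration of circular ligation products, stability
# classification and ORF-continuity checking.
#
# Ligase contract: only perfect 3-nt Watson-Crick overhang matches ligate;
# no blunt ligation, no mismatch tolerance.

#' Enumerate circular ligation products of a fragment pool
#'
#' Builds a directed graph with an edge from fragment end i to fragment end
#' j when i's right (bottom-strand) overhang is the Watson-Crick complement
#' demanded by j's left (top-strand) overhang, and enumerates every simple
#' circular walk (each fragment used at most once, in either orientation).
#' Products are deduplicated by canonical rotation and strand: a product
#' and its reverse complement are the same molecule. Junctions shared by
#' more than one fragment end are reported in the `diagnostics` attribute.
#'
#' @param fragments List of `tnt_fragment` objects (circular fragments are
#'   ignored; they cannot ligate).
#' @param max_products Safety cap on the number of enumerated products.
#' @return List of `tnt_product` objects, with attributes `diagnostics`
#'   (ambiguous-junction tibble) and `dangling` (overhangs with no partner).
#' @export
ligate_products <- function(fragments, max_products = 512L) {
  fragments <- Filter(function(f) !f$circular, fragments)
  n <- length(fragments)
  if (!n) {
    out <- list()
    attr(out, "diagnostics") <- empty_junction_diag()
    attr(out, "dangling") <- character()
    return(out)
  }
  # orientation table: 2 rows per fragment
  orient <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    orient[[2L * i - 1L]] <- list(id = i, flip = FALSE,
                                  frag = fragments[[i]])
    orient[[2L * i]] <- list(id = i, flip = TRUE,
                             frag = flip_fragment(fragments[[i]]))
  }
  left_of <- vapply(orient, function(o) o$frag$left_ov, character(1))
  right_junction <- vapply(orient, function(o)
    right_junction_top(o$frag), character(1))
  sticky <- nchar(left_of) == 3L & nchar(right_junction) == 3L
  # successors: orientation u can be followed by orientation v
  succ <- lapply(seq_along(orient), function(u) {
    if (!sticky[u]) return(integer(0))
    which(sticky & left_of == right_junction[u] &
            vapply(orient, function(o) o$id, integer(1)) !=
            orient[[u]]$id)
  })
  self_close <- vapply(seq_along(orient), function(u) {
    sticky[u] && identical(left_of[u], right_junction[u])
  }, logical(1))

  cycles <- list()
  # DFS: cycles are rooted at their smallest fragment id to avoid
  # rotational duplicates; both root orientations are explored and
  # strand-duplicates removed afterwards.
  walk <- function(path_orients, used) {
    if (length(cycles) >= max_products) return()
    u <- path_orients[[length(path_orients)]]
    root <- path_orients[[1L]]
    # close the cycle?
    if (identical(left_of[root], right_junction[u])) {
      cycles[[length(cycles) + 1L]] <<- path_orients
    }
    for (v in succ[[u]]) {
      vid <- orient[[v]]$id
      if (used[vid] || vid < orient[[root]]$id) next
      used[vid] <- TRUE
      walk(c(path_orients, v), used)
      used[vid] <- FALSE
    }
  }
  for (u in seq_along(orient)) {
    if (!sticky[u]) next
    used <- logical(n)
    used[orient[[u]]$id] <- TRUE
    if (self_close[u]) cycles[[length(cycles) + 1L]] <- u
    for (v in succ[[u]]) {
      vid <- orient[[v]]$id
      if (vid <= orient[[u]]$id) next
      used[vid] <- TRUE
      walk(c(u, v), used)
      used[vid] <- FALSE
    }
  }
  # dedup by the oriented-fragment cycle (rotation/strand invariant),
  # then assemble the survivors
  seen <- character(0)
  products <- list()
  for (cyc in cycles) {
    ids <- vapply(cyc, function(u) orient[[u]]$id, integer(1))
    flips <- vapply(cyc, function(u) orient[[u]]$flip, logical(1))
    key <- cycle_key(ids, flips)
    if (key %in% seen) next
    seen <- c(seen, key)
    products[[length(products) + 1L]] <-
      assemble_product(lapply(cyc, function(u) orient[[u]]))
  }
  # diagnostics: every physical end appears exactly once as a left
  # overhang across the two orientations, so a 3-mer counted twice is an
  # overhang shared by more than one fragment end
  lefts3 <- left_of[sticky]
  tab <- table(lefts3)
  amb <- names(tab)[tab > 1L]
  diag <- if (length(amb)) {
    tibble::tibble(junction = amb,
                   n_ends = as.integer(tab[amb]),
                   note = "overhang shared by more than one fragment end")
  } else empty_junction_diag()
  needed <- unique(right_junction[sticky])
  dangling <- setdiff(needed, unique(left_of[sticky]))
  attr(products, "diagnostics") <- diag
  attr(products, "dangling") <- dangling
  products
}

# Canonical key of a circular arrangement of oriented fragments: minimal
# over rotations of the cycle and of its strand-flipped reversal.
cycle_key <- function(ids, flips) {
  tok <- paste0(ids, ifelse(flips, "-", "+"))
  rtok <- rev(paste0(ids, ifelse(flips, "+", "-")))
  k <- length(tok)
  best <- NULL
  for (i in seq_len(k)) {
    for (t in list(tok, rtok)) {
      cand <- paste(t[c(i:k, seq_len(i - 1L))], collapse = "|")
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

# Two circular top strands describe the same molecule when one is a
# rotation of the other or of its reverse complement.
same_circular_sequence <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  bb <- paste0(b, b)
  grepl(a, bb, fixed = TRUE) || grepl(rc(a), bb, fixed = TRUE)
}

# A fragment is "clean" when it carries no unblocked recognition site of
# the enzyme: only clean fragments can take part in stable products, so
# the unmatched-overhang (dangling) diagnostic is computed over them.
fragment_is_clean <- function(f, enzyme) {
  vt <- paste0(fragment_top(f), rc_or_empty(f$right_ov))
  if (!nrow(f$marks)) {
    return(!length(scan_string(vt, enzyme$recognition)) &&
             !length(scan_string(vt, rc(enzyme$recognition))))
  }
  molf <- new_molecule_unsafe("fragment", vt, "linear",
                              marks = f$marks, features = empty_features())
  sites <- list_cut_sites(molf, enzyme)
  !any(!sites$blocked)
}

empty_junction_diag <- function() {
  tibble::tibble(junction = character(), n_ends = integer(),
                 note = character())
}

# Concatenate oriented fragments into a circular product molecule.
assemble_product <- function(oriented) {
  tops <- vapply(oriented, function(o) fragment_top(o$frag), character(1))
  lens <- nchar(tops)
  offs <- c(0L, cumsum(lens))[seq_along(lens)]
  N <- sum(lens)
  seqs <- paste0(tops, collapse = "")
  marks <- list()
  feats <- list()
  parts <- list()
  for (k in seq_along(oriented)) {
    f <- oriented[[k]]$frag
    if (nrow(f$marks)) {
      mk <- f$marks
      mk$position <- (mk$position + offs[k]) %% N
      marks[[k]] <- mk
    }
    if (nrow(f$features)) {
      ft <- f$features
      ft$start <- ft$start + offs[k]
      ft$end <- ft$end + offs[k]
      keep <- ft$end <= N # drop annotations running past the wrap point
      feats[[k]] <- ft[keep | ft$start < N, , drop = FALSE]
      feats[[k]]$end <- pmin(feats[[k]]$end, N)
    }
    parts[[k]] <- quick_tbl(
      slot = k,
      parent = paste(unique(f$provenance$parent), collapse = "+"),
      flipped = oriented[[k]]$flip,
      size = fragment_size(f),
      junction = f$left_ov)
  }
  mol <- new_molecule_unsafe("product", seqs, "circular",
                             marks = quick_bind(marks) %||% empty_marks(),
                             features = quick_bind(feats) %||%
                               empty_features())
  part_order <- quick_bind(parts)
  structure(list(molecule = mol, part_order = part_order,
                 junctions = part_order$junction, stable = NA),
            class = "tnt_product")
}

#' @export
print.tnt_product <- function(x, ...) {
  cat(sprintf("<tnt_product> %d bp circular, %d part(s): %s%s\n",
              dna_length(x$molecule), nrow(x$part_order),
              paste0(x$part_order$parent,
                     ifelse(x$part_order$flipped, "(-)", ""),
                     collapse = " - "),
              if (isTRUE(x$stable)) " [stable]" else ""))
  invisible(x)
}

# -- one-pot reaction --------------------------------------------------------

#' Simulate a one-pot digestion-ligation reaction
#'
#' Digests every pool molecule with the enzyme (respecting the current
#' methylation state), ligates the resulting fragments in all compatible
#' circular combinations, and classifies products: a product is *stable*
#' when it retains no unblocked, cuttable site of the reaction enzyme
#' (re-ligated input plasmids are therefore excluded: they remain
#' cleavable). Iterating digestion and ligation reaches this fixpoint after
#' a single round because re-digesting an unstable product regenerates
#' fragments already present in the pool.
#'
#' A product whose only remaining unblocked sites lie inside features of
#' type `"entry_flank"` is additionally flagged `entry_stable`: this is the
#' normal state of a library clone in the entry vector, which by design
#' keeps its dual-enzyme flanking sites.
#'
#' @param pool List of `tnt_dna` molecules (the reaction mix).
#' @param enzyme A `tnt_enzyme` (or name).
#' @param keep_unstable Keep unstable products in the result (for
#'   diagnostics); default drops them.
#' @return List with elements `products` (stable products; see
#'   `keep_unstable`), `summary` (tibble over all enumerated products),
#'   `diagnostics`, `dangling`.
#' @export
one_pot <- function(pool, enzyme, keep_unstable = FALSE) {
  if (inherits(pool, "tnt_dna")) pool <- list(pool)
  if (!length(pool)) stop("pool must be non-empty", call. = FALSE)
  if (is.character(enzyme)) enzyme <- tnt_enzyme(enzyme)
  frags <- list()
  uncut <- list()
  for (mol in pool) {
    fs <- digest(mol, enzyme)
    for (f in fs) {
      if (f$circular) uncut[[length(uncut) + 1L]] <- f
      else frags[[length(frags) + 1L]] <- f
    }
  }
  products <- ligate_products(frags)
  diag <- attr(products, "diagnostics")
  input_seqs <- vapply(pool, function(m) m$sequence, character(1))
  keep <- list()
  rows <- list()
  for (p in products) {
    if (!nrow(p$molecule$marks)) {
      # no marks, so nothing can be blocked: motif presence decides
      n_motifs <- length(scan_string(p$molecule$sequence,
                                     enzyme$recognition, TRUE)) +
        length(scan_string(p$molecule$sequence, rc(enzyme$recognition),
                           TRUE))
      stable <- n_motifs == 0L
      open_sites <- if (stable) NULL else
        list_cut_sites(p$molecule, enzyme)
    } else {
      open_sites <- list_cut_sites(p$molecule, enzyme)
      stable <- !any(!open_sites$blocked & open_sites$status == "ok")
    }
    if (!is.null(open_sites)) {
      open_sites <- open_sites[!open_sites$blocked &
                                 open_sites$status == "ok", , drop = FALSE]
    }
    entry_stable <- stable ||
      all_sites_in_entry_flanks(open_sites, p$molecule)
    is_input <- any(vapply(input_seqs, same_circular_sequence,
                           logical(1), a = p$molecule$sequence))
    p$stable <- stable
    p$entry_stable <- entry_stable
    p$is_reli_gated_input <- is_input
    rows[[length(rows) + 1L]] <- quick_tbl(
      parts = paste0(p$part_order$parent,
                     ifelse(p$part_order$flipped, "(-)", ""),
                     collapse = " - "),
      n_parts = nrow(p$part_order),
      length = dna_length(p$molecule),
      stable = stable, entry_stable = entry_stable,
      religated_input = is_input,
      has_stuffer = has_feature(p$molecule, "stuffer"))
    if ((stable || (entry_stable && !is_input)) && !is_input) {
      keep[[length(keep) + 1L]] <- p
    } else if (keep_unstable) {
      keep[[length(keep) + 1L]] <- p
    }
  }
  # dangling-junction diagnostic: computed over the fragments eligible
  # for stable products (no unblocked site), only when needed
  dangling <- character()
  if (!length(keep)) {
    clean <- Filter(function(f) fragment_is_clean(f, enzyme), frags)
    clean <- Filter(function(f)
      nchar(f$left_ov) == 3L && nchar(f$right_ov) == 3L, clean)
    lefts <- vapply(clean, function(f) f$left_ov, character(1))
    demands <- vapply(clean, right_junction_top, character(1))
    dangling <- sort(union(setdiff(demands, lefts),
                           setdiff(lefts, demands)))
  }
  list(products = keep,
       summary = if (length(rows)) dplyr::bind_rows(rows) else
         tibble::tibble(parts = character(), n_parts = integer(),
                        length = integer(), stable = logical(),
                        entry_stable = logical(),
                        religated_input = logical(),
                        has_stuffer = logical()),
       diagnostics = diag, dangling = dangling, uncut = uncut)
}

all_sites_in_entry_flanks <- function(open_sites, mol) {
  if (!nrow(open_sites)) return(TRUE)
  flanks <- mol$features[mol$features$type == "entry_flank", , drop = FALSE]
  if (!nrow(flanks)) return(FALSE)
  L <- dna_length(mol)
  all(vapply(seq_len(nrow(open_sites)), function(i) {
    s <- open_sites$rec_start[i]
    m <- 7L # generous: recognition start within a flank feature
    any(flanks$start <= s & s < flanks$end)
  }, logical(1)))
}

has_feature <- function(mol, type) {
  any(mol$features$type == type)
}

# lexicographically least rotation of the sequence or its reverse
# complement, used as a strand/rotation-invariant identity key
canonical_sequence <- function(seq) {
  min(min_rotation(seq), min_rotation(rc(seq)))
}

# Booth-style minimal rotation by iterative candidate refinement
min_rotation <- function(seq) {
  L <- nchar(seq)
  if (L <= 1L) return(seq)
  s2 <- paste0(seq, seq)
  chars <- strsplit(s2, "")[[1]]
  cand <- seq_len(L)
  offset <- 0L
  while (length(cand) > 1L && offset < L) {
    cs <- chars[cand + offset]
    m <- min(cs)
    cand <- cand[cs == m]
    offset <- offset + 1L
    if (length(cand) > 1L && offset >= 24L) {
      # resolve remaining ties by direct comparison (rare)
      subs <- vapply(cand, function(i) substr(s2, i, i + L - 1L),
                     character(1))
      return(min(subs))
    }
  }
  substr(s2, cand[1], cand[1] + L - 1L)
}

# -- ORF continuity ----------------------------------------------------------

#' Check open-reading-frame continuity across assembly junctions
#'
#' Verifies that coding spans joined through 3-nt junctions translate as a
#' single frame: every junction contributes exactly one codon, every span
#' length is a multiple of 3, and the concatenated region contains no
#' internal stop codon.
#'
#' @param product A `tnt_product` (or `tnt_dna` molecule).
#' @param cds_spans Tibble or data.frame with columns `start`, `end`
#'   (0-based, half-open, ascending, on the top strand of the product).
#' @return List with `ok` (logical) and `report` (per-span tibble with a
#'   `frameshift_at` column; NA when in frame).
#' @export
check_orf_continuity <- function(product, cds_spans) {
  mol <- if (inherits(product, "tnt_product")) product$molecule else product
  cds_spans <- tibble::as_tibble(cds_spans)
  L <- dna_length(mol)
  if (any(cds_spans$start < 0L) || any(cds_spans$end > L)) {
    stop("cds span outside product", call. = FALSE)
  }
  cds_spans <- cds_spans[order(cds_spans$start), , drop = FALSE]
  lens <- cds_spans$end - cds_spans$start
  shift <- which(lens %% 3L != 0L)
  report <- tibble::tibble(
    start = cds_spans$start, end = cds_spans$end, length = lens,
    in_frame = lens %% 3L == 0L,
    frameshift_at = ifelse(lens %% 3L == 0L, NA_integer_, cds_spans$end))
  gaps_ok <- TRUE
  if (nrow(cds_spans) > 1L) {
    gaps <- cds_spans$start[-1L] - cds_spans$end[-nrow(cds_spans)]
    gaps_ok <- all(gaps >= 0L & gaps %% 3L == 0L)
  }
  ok <- all(report$in_frame) && gaps_ok
  stops <- NA
  if (ok) {
    region <- substr(mol$sequence, cds_spans$start[1] + 1L,
                     cds_spans$end[nrow(cds_spans)])
    prot <- translate_dna(region, 0L)
    internal <- substr(prot, 1L, nchar(prot) - 1L)
    stops <- grepl("\\*", internal)
    ok <- ok && !stops
  }
  list(ok = ok, report = report, gaps_in_frame = gaps_ok,
       internal_stop = isTRUE(stops))
}
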