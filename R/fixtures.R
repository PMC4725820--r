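# Synthetic fixtures: molecules with recognition sites placed at
# prescribed cut coordinates (reproducing the methylation band-merge
# geometries), random element libraries, and run configuration.

#' Build a molecule with sites at prescribed cut coordinates
#'
#' Generates a random molecule and stamps one EarI site per requested
#' top-strand cut coordinate. Per-site contexts control the composite
#' methylation geometry: `"plain"` (no overlap), `"M.SacI"` (GAGCTC
#' overlapping the site), `"M.TaqI"` (TCGA overlapping the downstream
#' cleavage region). The filler is scrubbed so no unintended recognition
#' or methyltransferase motif remains.
#'
#' @param id Molecule id.
#' @param length Total length in bp.
#' @param cuts Integer vector of top-strand cut coordinates (each site's
#'   top nick position).
#' @param topology `"circular"` or `"linear"`.
#' @param contexts Character vector (recycled) matching `cuts`:
#'   "plain", "M.SacI" or "M.TaqI".
#' @param seed Seed for the filler sequence.
#' @return A `tnt_dna` molecule with `site` features at the stamped sites.
#' @export
make_band_fixture <- function(id, length, cuts,
                              topology = c("circular", "linear"),
                              contexts = "plain", seed = 1L) {
  topology <- match.arg(topology)
  contexts <- rep_len(contexts, length(cuts))
  if (length(cuts) > 1L) {
    gaps <- diff(sort(cuts))
    if (any(gaps < 30L)) stop("infeasible placement: sites closer than 30 nt",
                              call. = FALSE)
  }
  if (any(cuts < 15L) || any(cuts > length - 15L)) {
    stop("infeasible placement: cut too close to the molecule end",
         call. = FALSE)
  }
  stamp_for <- function(ctx) {
    switch(ctx,
           plain = list(offset = -8L, piece = "ACTCTTCA"),
           M.SacI = list(offset = -10L, piece = "GAGCTCTTCA"),
           M.TaqI = list(offset = -8L, piece = "ACTCTTCGAA"),
           stop("unknown context: ", ctx, call. = FALSE))
  }
  for (try_seed in 0:24) {
    filler <- random_dna(length, seed = seed + 1000L * try_seed)
    filler <- scrub_motifs(filler, c("CTCTTC", "GAAGAG", "GAGCTC", "TCGA"),
                           circular = topology == "circular")
    chars <- strsplit(filler, "")[[1]]
    for (k in seq_along(cuts)) {
      st <- stamp_for(contexts[k])
      at <- cuts[k] + st$offset # piece positioned so CTCTTC cut == cuts[k]
      idx <- at + seq_len(nchar(st$piece))
      chars[idx] <- strsplit(st$piece, "")[[1]]
    }
    seqs <- paste0(chars, collapse = "")
    circ <- topology == "circular"
    ok <- identical(sort(scan_string(seqs, "CTCTTC", circ)),
                    sort(cuts - 7L)) &&
      !length(scan_string(seqs, "GAAGAG", circ)) &&
      identical(length(scan_string(seqs, "GAGCTC", circ)),
                sum(contexts == "M.SacI")) &&
      identical(length(scan_string(seqs, "TCGA", circ)),
                sum(contexts == "M.TaqI"))
    if (ok) {
      feats <- tibble::tibble(
        label = paste0("EarI site (", contexts, ")"),
        start = cuts - 7L - ifelse(contexts == "M.SacI", 3L, 1L),
        end = cuts + ifelse(contexts == "M.TaqI", 2L, 0L),
        strand = "+", type = "site")
      return(dna_molecule(id, seqs, topology, features = feats))
    }
  }
  stop("could not place sites cleanly; adjust coordinates", call. = FALSE)
}

#' Circular band-merge fixture (6,435 bp)
#'
#' The circular plasmid geometry used to demonstrate M.SacI blocking:
#' EarI top-strand cuts at 100, 348 and 1657, the 348-site overlapping a
#' GAGCTC motif. Unmethylated digestion gives fragments of 248, 1309 and
#' 4878 bp; with M.SacI methylation the 348-site is blocked and the 248
#' and 1309 bp fragments merge into one 1557 bp band.
#'
#' @param seed Filler seed.
#' @return A circular `tnt_dna`.
#' @export
fixture_circular_saci <- function(seed = 1L) {
  make_band_fixture("pET28-like-M.SacI-fixture", 6435L,
                    cuts = c(100L, 348L, 1657L), topology = "circular",
                    contexts = c("plain", "M.SacI", "plain"), seed = seed)
}

#' Linear band-merge fixture (1,055 bp)
#'
#' The linear PCR-product geometry used to demonstrate M.TaqI blocking:
#' EarI cuts at 355 and 805, the 805-site overlapping a TCGA motif.
#' Unmethylated digestion gives 355, 450 and 250 bp; with M.TaqI
#' methylation the 450 and 250 bp fragments merge into one 700 bp band.
#'
#' @param seed Filler seed.
#' @return A linear `tnt_dna`.
#' @export
fixture_linear_taqi <- function(seed = 1L) {
  make_band_fixture("PCR-1055-M.TaqI-fixture", 1055L,
                    cuts = c(355L, 805L), topology = "linear",
                    contexts = c("plain", "M.TaqI"), seed = seed)
}

# -- random element libraries ------------------------------------------------

# Make an element body safe inside its cloning contexts: no recognition
# motif may appear in ACC|elem|GAT (sense) or ATC|rc(elem)|GGT (antisense).
scrub_element_seq <- function(seq, cds = FALSE, max_iter = 100L) {
  pad_l <- "ATCACC"
  pad_r <- "GATGGT"
  chars <- strsplit(seq, "")[[1]]
  for (it in seq_len(max_iter)) {
    padded <- paste0(pad_l, paste0(chars, collapse = ""), pad_r)
    bad <- c(scan_string(padded, "CTCTTC"), scan_string(padded, "GAAGAG"))
    if (!length(bad)) {
      out <- paste0(chars, collapse = "")
      if (!cds) return(out)
      prot <- translate_dna(out)
      if (!grepl("\\*", substr(prot, 1, nchar(prot) - 1L))) return(out)
      # break the first internal stop by swapping its middle base
      at <- (regexpr("\\*", prot) - 1L) * 3L + 2L
      chars[at] <- switch(chars[at], A = "C", C = "A", G = "C", T = "C")
      next
    }
    # mutate the element base nearest the middle of the first bad hit
    mid <- bad[1] + 3L # 1-based-ish centre in padded coordinates
    pos <- min(max(mid - nchar(pad_l), 1L), length(chars))
    chars[pos] <- switch(chars[pos], A = "G", C = "T", G = "A", T = "C")
  }
  stop("could not scrub element sequence", call. = FALSE)
}

#' Generate a random element library
#'
#' Produces `n` synthetic elements with ids `E01`, `E02`, ... Elements are
#' free of internal (G)CTCTTC sites (including across the signature
#' boundaries they will acquire in the vectors); CDS-category elements
#' have length a multiple of 3 and no internal stop codon.
#'
#' @param n Number of elements.
#' @param seed RNG seed.
#' @param min_len,max_len Length range in bp.
#' @param categories Categories to cycle through.
#' @return List with `molecules` (named list of `tnt_element`) and
#'   `manifest` (tibble: id, category, length, domesticated).
#' @export
random_element_library <- function(n, seed = 1L, min_len = 90L,
                                   max_len = 240L,
                                   categories = c("CDS", "URR",
                                                  "terminator", "tag")) {
  stopifnot(n >= 1L, min_len >= 30L, max_len >= min_len)
  mols <- list()
  rows <- list()
  with_private_seed(seed, {
    for (i in seq_len(n)) {
      id <- sprintf("E%02d", i)
      category <- categories[(i - 1L) %% length(categories) + 1L]
      len <- sample(min_len:max_len, 1L)
      if (category == "CDS") {
        len <- max(3L * (len %/% 3L), 30L)
        codons <- setdiff(names(Biostrings::GENETIC_CODE)[
          Biostrings::GENETIC_CODE != "*"], character())
        body <- paste0(sample(codons, len %/% 3L, replace = TRUE),
                       collapse = "")
        body <- scrub_element_seq(body, cds = TRUE)
      } else {
        body <- scrub_element_seq(paste0(
          sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""))
      }
      el <- element_record(id, body, category = category,
                           domesticated = TRUE)
      mols[[id]] <- el
      rows[[i]] <- tibble::tibble(id = id, category = category,
                                  length = nchar(body),
                                  domesticated = TRUE)
    }
  })
  list(molecules = mols, manifest = dplyr::bind_rows(rows))
}

#' Write the canned fixtures and a random element library to disk
#'
#' @param dir Output directory (created if needed).
#' @param n_elements Number of library elements.
#' @param seed RNG seed.
#' @return Tibble of written files, invisibly.
#' @export
make_fixtures <- function(dir, n_elements = 10L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  circ <- fixture_circular_saci(seed)
  lin <- fixture_linear_taqi(seed)
  f1 <- file.path(dir, "fixture-circular-saci.gb")
  f2 <- file.path(dir, "fixture-linear-taqi.gb")
  write_genbank(circ, f1)
  write_genbank(lin, f2)
  lib <- random_element_library(n_elements, seed = seed)
  f3 <- file.path(dir, "element-library.fasta")
  write_fasta(unname(lib$molecules), f3)
  f4 <- file.path(dir, "element-manifest.tsv")
  utils::write.table(lib$manifest, f4, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tibble::tibble(file = c(f1, f2, f3, f4)))
}

# -- run configuration -------------------------------------------------------

RUN_CONFIG_KEYS <- c("signatures", "planner", "stochastic", "output_dir")

#' Default run configuration
#'
#' @return Nested list: signature overrides, planner defaults (first
#'   family), stochastic defaults (p_cut, inhibition, n, seed).
#' @export
run_config_default <- function() {
  list(signatures = as.list(unclass(signature_set())),
       planner = list(first_family = "alpha"),
       stochastic = list(p_cut = 0.625, inhibition = 0.759,
                         n = 10000L, seed = 1L),
       output_dir = ".")
}

#' Load a run configuration from YAML
#'
#' Unknown top-level keys are rejected; known keys are merged over the
#' defaults and validated.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
run_config_load <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(run_config_default(), cfg)
  do.call(signature_set, out$signatures) # validates
  stopifnot(out$planner$first_family %in% c("alpha", "omega"),
            out$stochastic$p_cut >= 0, out$stochastic$p_cut <= 1,
            out$stochastic$inhibition >= 0, out$stochastic$inhibition <= 1)
  out
}
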