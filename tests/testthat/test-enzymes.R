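test_that("methyltransferases mark both strands of their palindromic motifs", {
  m <- apply_methyltransferase(dna_molecule("t", "ATCGAT"), "M.TaqI")
  expect_identical(nrow(m$marks), 2L)
  expect_setequal(paste(m$marks$strand, m$marks$position),
                  c("top 4", "bottom 1")) # adenines of TCGA
  expect_true(all(m$marks$kind == "m6A"))

  s <- apply_methyltransferase(dna_molecule("t", "AACGTT"), "M.SssI")
  expect_identical(nrow(s$marks), 2L)
  expect_true(all(s$marks$kind == "m5C"))

  none <- apply_methyltransferase(dna_molecule("t", "AAAATTTT"), "M.TaqI")
  expect_identical(nrow(none$marks), 0L)

  twice <- apply_methyltransferase(m, "M.TaqI")
  expect_identical(twice$marks, m$marks) # idempotent
})

test_that("cut coordinates follow the N1/N4 downstream geometry", {
  cs <- list_cut_sites(dna_molecule("x", "AACTCTTCAAAAA"), "EarI")
  expect_identical(nrow(cs), 1L)
  expect_identical(cs$cut_top, 9L)    # one N after the recognition 3' end
  expect_identical(cs$cut_bottom, 12L) # three further
  # bottom-strand site mirrored
  cs2 <- list_cut_sites(dna_molecule("y", "AAAAAGAAGAGAA"), "EarI")
  expect_identical(cs2$strand, "bottom")
  expect_identical(cs2$cut_top, 1L)
  expect_identical(cs2$cut_bottom - cs2$cut_top, 3L)
})

test_that("M.TaqI methylation of the composite context blocks cleavage", {
  m <- apply_methyltransferase(dna_molecule("x", "GCTCTTCGAAAA"), "M.TaqI")
  cs <- list_cut_sites(m, "EarI")
  expect_true(all(cs$blocked))
  expect_identical(unique(cs$efficiency), 1)
  # without marks the same site cuts
  cs0 <- list_cut_sites(dna_molecule("x", "GCTCTTCGAAAA"), "EarI")
  expect_false(any(cs0$blocked))
})

test_that("every LguI site is nested within an EarI site", {
  set.seed(31)
  for (i in 1:8) {
    s <- paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
    mol <- dna_molecule("r", s)
    lg <- list_cut_sites(mol, "LguI")
    ea <- list_cut_sites(mol, "EarI")
    expect_true(all(lg$cut_top %in% ea$cut_top))
  }
})

test_that("terminal sites whose cuts run off a linear molecule are flagged", {
  cs <- list_cut_sites(dna_molecule("t", "AACTCTTCAA"), "EarI")
  expect_identical(cs$status, "uncuttable_terminal")
  frags <- digest(dna_molecule("t", "AACTCTTCAA"), "EarI")
  expect_length(frags, 1L) # reported but not cut
})

test_that("LguI promiscuity context is a warning, not a cut", {
  mol <- dna_molecule("p", "AAAACTCTTCAAAAAA")
  lg <- list_cut_sites(mol, "LguI")
  expect_identical(nrow(lg), 0L) # aaCTCTTC is not an LguI site
  ea <- list_cut_sites(mol, "EarI")
  expect_false(ea$warn_promiscuity) # EarI has no such context
  # LguI flags its aa context on a true GCTCTTC site
  mol2 <- dna_molecule("p2", "AAAAGCTCTTCAAAAAA")
  lg2 <- list_cut_sites(mol2, "LguI")
  expect_identical(nrow(lg2), 1L)
  expect_true(lg2$warn_promiscuity)
})

test_that("band-merge fixtures reproduce the published fragment patterns", {
  circ <- fixture_circular_saci()
  expect_identical(dna_length(circ), 6435L)
  expect_setequal(tidy_digest(digest(circ, "EarI"))$size,
                  c(248L, 1309L, 4878L))
  blocked <- apply_methyltransferase(circ, "M.SacI")
  expect_setequal(tidy_digest(digest(blocked, "EarI"))$size,
                  c(1557L, 4878L))

  lin <- fixture_linear_taqi()
  expect_identical(dna_length(lin), 1055L)
  expect_setequal(tidy_digest(digest(lin, "EarI"))$size,
                  c(355L, 450L, 250L))
  blocked2 <- apply_methyltransferase(lin, "M.TaqI")
  expect_setequal(tidy_digest(digest(blocked2, "EarI"))$size,
                  c(700L, 355L))
})

test_that("digestion conserves length and respects topology counts", {
  set.seed(41)
  for (i in 1:10) {
    topo <- sample(c("linear", "circular"), 1)
    mol <- make_band_fixture("r", 900L,
                             cuts = sort(sample(seq(60L, 840L, by = 60L),
                                                sample(1:4, 1))),
                             topology = topo, seed = i)
    frags <- digest(mol, "EarI")
    sizes <- tidy_digest(frags)$size
    expect_identical(sum(sizes), 900L)
    k <- nrow(attr(frags, "sites"))
    expect_length(frags, if (topo == "circular") k else k + 1L)
  }
})

test_that("a circular molecule without sites is returned as one uncut circle", {
  mol <- dna_molecule("empty", strrep("ACGG", 50), "circular")
  frags <- digest(mol, "EarI")
  expect_length(frags, 1L)
  expect_true(frags[[1]]$circular)
  expect_identical(frags[[1]]$core, mol$sequence)
})

test_that("adding methylation marks never increases fragment counts", {
  set.seed(51)
  for (i in 1:6) {
    mol <- make_band_fixture("r", 700L, cuts = c(120L, 340L, 560L),
                             topology = "linear",
                             contexts = sample(c("plain", "M.TaqI",
                                                 "M.SacI"), 3,
                                               replace = TRUE),
                             seed = i + 100L)
    n0 <- length(digest(mol, "EarI"))
    for (mt in c("M.TaqI", "M.SacI", "M.SssI")) {
      mol <- apply_methyltransferase(mol, mt)
      expect_lte(length(digest(mol, "EarI")), n0)
    }
  }
})

test_that("digestion is invariant under rotation of circular inputs", {
  mol <- fixture_circular_saci()
  sizes <- sort(tidy_digest(digest(mol, "EarI"))$size)
  for (k in c(99L, 1000L, 4321L)) {
    rot <- tntsim:::rotate_molecule(mol, k)
    expect_identical(sort(tidy_digest(digest(rot, "EarI"))$size), sizes)
  }
})

test_that("overlapping cuts raise a conflicting-cuts error", {
  mol <- dna_molecule("clash", "CTCTTCAAAGAAGAGAAAA")
  expect_error(digest(mol, "EarI"), "conflicting-cuts")
})

test_that("partial digestion reduces to full digestion at probability 1", {
  lin <- fixture_linear_taqi()
  res <- digest_partial(lin, "EarI",
                        per_site_probability = c("355" = 1, "805" = 1),
                        n_molecules = 50L, seed = 3L)
  expect_true(all(res$site_summary$cut_fraction == 1))
  expect_setequal(res$fragment_population$size, c(355L, 450L, 250L))
})

test_that("partial digestion matches the exact binomial distribution", {
  lin <- fixture_linear_taqi()
  n <- 10000L
  res <- digest_partial(lin, "EarI",
                        per_site_probability = c("805" = 0.625),
                        n_molecules = n, seed = 7L)
  frac <- res$site_summary$cut_fraction[
    res$site_summary$cut_top == 805L]
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.625) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("protection scales cut probability by one minus the inhibition", {
  lin <- fixture_linear_taqi()
  n <- 10000L
  inh <- 0.759
  res <- digest_partial(lin, "EarI",
                        per_site_probability =
                          c("355" = 0.625, "805" = 0.625 * (1 - inh)),
                        n_molecules = n, seed = 9L)
  f <- res$site_summary
  ratio <- f$cut_fraction[f$cut_top == 805L] /
    f$cut_fraction[f$cut_top == 355L]
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.625 * (1 - inh)) / n /
    0.625
  expect_gte(ratio, ci[1] * 0.9)
  expect_lte(ratio, ci[2] * 1.1)
  expect_error(digest_partial(lin, "EarI", c("999" = 0.5)), "unknown site")
})
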