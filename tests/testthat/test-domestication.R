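test_that("site scanning deduplicates the two strand representations", {
  expect_identical(scan_internal_sites("AAACTCTTCAAA")$strand, "top")
  hit <- scan_internal_sites("AAAGAAGAGAAA")
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$strand, "bottom")
  ext <- scan_internal_sites(paste0(strrep("A", 12), "GCTCTTC",
                                    strrep("A", 12)))
  expect_identical(nrow(ext), 1L)
  expect_true(ext$extended)
  expect_identical(nchar(ext$context), 26L)
  none <- scan_internal_sites("ACGTACGTACGT")
  expect_identical(nrow(none), 0L)
})

test_that("recoding picks the most preferred synonymous codon", {
  r1 <- domesticate("CTCTTC") # Leu-Phe
  expect_identical(r1$sequence, "CTGTTC")
  expect_identical(nrow(r1$edits), 1L)
  expect_identical(r1$edits$aa, "L")
  r2 <- domesticate("GAAGAG") # Glu-Glu
  expect_identical(r2$sequence, "GAAGAA")
  expect_identical(nrow(r2$edits), 1L)
  clean <- domesticate("ATGGCTGCA")
  expect_identical(clean$sequence, "ATGGCTGCA")
  expect_identical(nrow(clean$edits), 0L)
})

test_that("recoding preserves translation and removes every site", {
  set.seed(101)
  for (i in 1:40) {
    cds <- random_cds_with_sites(n_codons = sample(30:100, 1),
                                 n_sites = sample(1:3, 1))
    n_sites <- nrow(scan_internal_sites(cds))
    res <- domesticate(cds)
    expect_identical(nrow(scan_internal_sites(res$sequence)), 0L)
    expect_identical(translate_dna(res$sequence), translate_dna(cds))
    # one edit per removable site, never more
    expect_lte(nrow(res$edits), n_sites)
    # idempotent
    again <- domesticate(res$sequence)
    expect_identical(again$sequence, res$sequence)
    expect_identical(nrow(again$edits), 0L)
  }
})

test_that("recoding rejects malformed coding sequences", {
  expect_error(domesticate("CTCTT"), "multiple of 3")
  expect_error(domesticate("ATGTAAATG"), "internal stop")
})

test_that("masking oligos are 26 nt on the GCTCTTC-reading strand", {
  set.seed(102)
  filler <- function(n) paste0(sample(c("A", "C"), n, replace = TRUE),
                               collapse = "")
  # top-strand site
  s_top <- paste0(filler(40), "GCTCTTC", filler(40))
  sites <- scan_internal_sites(s_top)
  oligo <- design_blindspot(s_top, sites[1, ], sites)
  expect_identical(nchar(oligo$sequence), 26L)
  expect_identical(oligo$orientation, "sense")
  # the oligo is an exact substring of its own strand (0 mismatches)
  expect_true(grepl(oligo$sequence, s_top, fixed = TRUE))
  # bottom-strand site (sense strand reads GAAGAGC): use the antisense
  s_bot <- paste0(filler(40), "GAAGAGC", filler(40))
  sites_b <- scan_internal_sites(s_bot)
  oligo_b <- design_blindspot(s_bot, sites_b[1, ], sites_b)
  expect_identical(nchar(oligo_b$sequence), 26L)
  expect_identical(oligo_b$orientation, "antisense")
  expect_true(grepl(oligo_b$sequence, oracle_rc(s_bot), fixed = TRUE))
  expect_true(grepl("GCTCTTC", oligo_b$sequence, fixed = TRUE))
})

test_that("identical site contexts trigger the 4-mismatch specificity floor", {
  # two copies of the same 36-mer: both 26-nt site windows are identical
  unit <- paste0("CCATAC", "ACGATCAGAATG", "CTCTTC", "GTACCGAT", "CCTG")
  s <- paste0(unit, unit)
  sites <- scan_internal_sites(s)
  expect_identical(nrow(sites), 2L)
  oligo <- design_blindspot(s, sites[1, ], sites)
  expect_identical(oligo$mismatch_profile$mismatches, 0L)
  expect_match(oligo$warnings, "specificity floor")
  # ample mismatches: no warning
  set.seed(103)
  s2 <- paste0(substr(s, 1, 60),
               paste0(sample(c("A", "C", "G", "T"), 30, TRUE),
                      collapse = ""))
  sites2 <- scan_internal_sites(s2)
  if (nrow(sites2) == 1L) {
    o2 <- design_blindspot(s2, sites2[1, ], sites2)
    expect_length(o2$warnings, 0L)
  }
})

test_that("truncated flanks are a design error", {
  s <- paste0("GCTCTTC", strrep("A", 40))
  sites <- scan_internal_sites(s)
  expect_error(design_blindspot(s, sites[1, ], sites), "11/8")
})

test_that("the inhibition coefficient is the matched-mismatched margin", {
  expect_equal(inhibition_coefficient(75.9, 8.3), 67.6)
  expect_equal(inhibition_coefficient(42, 42), 0)
  expect_equal(inhibition_coefficient(100, 0), 100)
  expect_error(inhibition_coefficient(120, 5))
})

test_that("blindspot simulation matches closed-form expectations", {
  lin <- fixture_linear_taqi() # vector-like site at 355, internal at 805
  n <- 10000L
  # full protection: intended fraction = p_cut expectation on vector sites
  full <- simulate_blindspot(lin, "EarI", protected_sites = 805L,
                             p_cut = 0.625, inhibition = 1, n = n,
                             seed = 5L)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.625) / n
  expect_gte(full$frac_intended, ci[1])
  expect_lte(full$frac_intended, ci[2])
  expect_equal(full$frac_intended_given_vector_cut, 1)
  # no protection: conditional fraction ~ (1 - p_cut)
  none <- simulate_blindspot(lin, "EarI", protected_sites = 805L,
                             p_cut = 0.625, inhibition = 0, n = n,
                             seed = 5L)
  expect_gt(none$frac_intended_given_vector_cut, 0.345)
  expect_lt(none$frac_intended_given_vector_cut, 0.405)
  expect_error(simulate_blindspot(lin, "EarI", protected_sites = 999L),
               "unknown")
})

test_that("the intended-product fraction is monotone in the inhibition", {
  lin <- fixture_linear_taqi()
  grid <- seq(0, 1, by = 0.25)
  fr <- vapply(grid, function(inh)
    simulate_blindspot(lin, "EarI", protected_sites = 805L,
                       p_cut = 0.625, inhibition = inh, n = 4000L,
                       seed = 11L)$frac_intended, numeric(1))
  expect_true(all(diff(fr) >= 0))
})
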