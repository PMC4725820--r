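test_that("signature sets enforce the grammar constraints", {
  expect_s3_class(signature_set(), "tnt_signature_set")
  # reverse-complement pairs are rejected (cross-ligation risk)
  expect_error(signature_set(s3 = "AGT", s4 = "ACT"), "reverse complement")
  # non-adenine leading base violates the TCGA-overlap rule
  expect_error(signature_set(s1 = "GCC"), "adenine")
  expect_error(signature_set(s1 = "AC"), "3-nt")
  expect_error(signature_set(s1 = "ACC", s2 = "ACC"), "distinct")
})

test_that("the registry holds 17 members with the published partition", {
  reg <- build_registry()
  expect_identical(nrow(reg), 17L)
  expect_identical(sum(reg$family == "entry"), 1L)
  expect_identical(sum(reg$family == "alpha"), 8L)
  expect_identical(sum(reg$family == "omega"), 8L)
  expect_identical(unique(reg$resistance[reg$family == "entry"]),
                   "carbenicillin")
  expect_identical(unique(reg$resistance[reg$family == "alpha"]),
                   "spectinomycin")
  expect_identical(unique(reg$resistance[reg$family == "omega"]),
                   "kanamycin")
  # enzymes alternate between the families
  expect_identical(unique(reg$accept_enzyme[reg$family == "alpha"]), "EarI")
  expect_identical(unique(reg$release_enzyme[reg$family == "alpha"]),
                   "LguI")
  expect_identical(unique(reg$accept_enzyme[reg$family == "omega"]), "LguI")
  expect_identical(unique(reg$release_enzyme[reg$family == "omega"]),
                   "EarI")
  # release flanks per variant
  a1 <- reg[reg$name == "alpha1A", ]
  expect_identical(c(a1$release_left, a1$release_right), c("s1", "s3"))
  b <- reg[reg$name == "omegaB", ]
  expect_identical(c(b$release_left, b$release_right), c("s3", "s4"))
  expect_true(all(reg$requires_methylated_propagation ==
                    (reg$family == "alpha")))
  expect_identical(unique(reg$release_site_upstream_context[
    reg$family == "omega"]), "cc")
  # registry built twice is identical (deterministic order)
  expect_identical(build_registry()$name, reg$name)
})

test_that("a methylated alpha member excises only its stuffer with EarI", {
  p <- make_member_plasmid("alpha1A", tnt_registry, backbone_length = 400L)
  sites <- list_cut_sites(p, "EarI")
  expect_identical(sum(!sites$blocked), 2L) # accept sites only
  frags <- digest(p, "EarI")
  expect_length(frags, 2L)
  kinds <- vapply(frags, function(f)
    if (any(f$features$type == "stuffer")) "stuffer" else "backbone",
    character(1))
  expect_setequal(kinds, c("stuffer", "backbone"))
  # composite release sites stay uncut while methylated...
  expect_true(all(sites$blocked[sites$efficiency == 1]))
  # ...and cut with LguI once marks are erased, exposing release flanks
  rel <- digest(erase_marks(p), "LguI")
  expect_length(rel, 2L)
  stuffer_frag <- Filter(function(f) any(f$features$type == "stuffer"),
                         rel)[[1]]
  sigs <- attr(tnt_registry, "signatures")
  expect_identical(stuffer_frag$left_ov, sigs$s1)             # s1
  expect_identical(oracle_rc(stuffer_frag$right_ov), sigs$s3) # s3
})

test_that("omega members use the cc release context, not aa", {
  p <- make_member_plasmid("omega1A", tnt_registry, backbone_length = 400L)
  expect_true(grepl("CCCTCTTC", p$sequence))
  expect_false(grepl("AACTCTTC", p$sequence))
  # accept with LguI exposes the standard s1/s2 junctions
  frags <- digest(p, "LguI")
  expect_length(frags, 2L)
  bb <- Filter(function(f) any(f$features$type == "backbone"), frags)[[1]]
  sigs <- attr(tnt_registry, "signatures")
  expect_identical(bb$left_ov, oracle_rc(sigs$s2)) # downstream of s2 cut
  expect_identical(oracle_rc(bb$right_ov), sigs$s1)
})

test_that("every member's accept digestion opens exactly two sites", {
  for (nm in tnt_registry$name) {
    p <- make_member_plasmid(nm, tnt_registry, backbone_length = 300L)
    member <- tnt_registry[tnt_registry$name == nm, ]
    enz <- if (member$family == "alpha") "EarI"
    else if (member$family == "omega") "LguI" else "EarI"
    sites <- list_cut_sites(p, enz)
    active <- sites[!sites$blocked & sites$status == "ok", ]
    expect_identical(length(unique(active$cut_top)), 2L)
  }
})

test_that("a stuffer with an internal site is rejected", {
  expect_error(
    make_member_plasmid("alpha1A", tnt_registry,
                        stuffer = paste0(strrep("ACGG", 20), "CTCTTC",
                                         strrep("ACGG", 20))),
    "internal unprotected")
})

test_that("assemblies re-enter the loop as s1/s2-flanked inserts", {
  # join-closure: a binary alpha assembly received in omega releases an
  # insert flanked by s1 and s2 again
  lib <- random_element_library(2, seed = 81)
  mk <- function(id, member) {
    entry <- make_entry_clone(lib$molecules[[id]], tnt_registry,
                              backbone_length = 250L)
    dest <- make_member_plasmid(member, tnt_registry,
                                backbone_length = 300L)
    erase_marks(one_pot(list(entry, dest), "EarI")$products[[1]]$molecule)
  }
  a <- mk("E01", "alpha1A")
  b <- mk("E02", "alpha2")
  dest <- make_member_plasmid("omega1A", tnt_registry,
                              backbone_length = 300L)
  pot <- one_pot(list(a, b, dest), "LguI")
  expect_length(pot$products, 1L)
  joined <- pot$products[[1]]$molecule
  # the new construct itself releases with EarI through its variant
  # flanks (1A: s1 left, s3 right), ready for the next round
  rel <- digest(joined, "EarI")
  ins <- Filter(function(f) any(f$features$type == "element"), rel)
  expect_length(ins, 1L)
  sigs <- attr(tnt_registry, "signatures")
  expect_identical(ins[[1]]$left_ov, sigs$s1)
  expect_identical(oracle_rc(ins[[1]]$right_ov), sigs$s3)
  prov <- tntsim:::product_provenance(joined)
  expect_identical(prov$id, c("E01", "E02"))
  # and the loop closes: the joined construct (released with flanks
  # s1/s3 from its 1A member) pairs with an omega2-held element (s3/s2)
  # to enter an alpha member for the next round
  lib2 <- random_element_library(3, seed = 82)
  entry3 <- make_entry_clone(lib2$molecules$E03, tnt_registry,
                             backbone_length = 250L)
  om2 <- make_member_plasmid("omega2", tnt_registry,
                             backbone_length = 300L)
  partner <- one_pot(list(entry3, om2), "LguI")$products[[1]]$molecule
  dest2 <- make_member_plasmid("alpha1A", tnt_registry,
                               backbone_length = 300L)
  pot2 <- one_pot(list(joined, partner, dest2), "EarI")
  expect_length(pot2$products, 1L)
  expect_identical(tntsim:::product_provenance(
    pot2$products[[1]]$molecule)$id, c("E01", "E02", "E03"))
})
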