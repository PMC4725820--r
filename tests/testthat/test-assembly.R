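test_that("two fragments with one compatible junction pair circularise", {
  set.seed(61)
  f1 <- random_fragment("ACC", "GGT") # right demands rc(GGT) = ACC
  f2 <- random_fragment("ACC", "GGT")
  prods <- ligate_products(list(f1, f2))
  canon <- product_canon(prods)
  expect_true(length(prods) >= 1L)
  expect_identical(canon, oracle_circles(list(f1, f2)))
})

test_that("fragments with disjoint overhang alphabets give no products", {
  set.seed(62)
  f1 <- random_fragment("ACC", "TTG")
  f2 <- random_fragment("GGA", "CCT")
  expect_length(ligate_products(list(f1, f2)), 0L)
})

test_that("no 3-nt overhang can be self-complementary", {
  all3 <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                            b2 = c("A", "C", "G", "T"),
                            b3 = c("A", "C", "G", "T")), 1, paste0,
                collapse = "")
  expect_false(any(vapply(all3, function(x) x == oracle_rc(x),
                          logical(1))))
})

test_that("ligation product sets match the brute-force oracle (<= 4 fragments)", {
  set.seed(63)
  overhangs <- c("ACC", "GAT", "AAT", "ACT", "GGT", "ATC")
  for (rep in 1:12) {
    n <- sample(2:4, 1)
    frags <- lapply(seq_len(n), function(i)
      random_fragment(sample(overhangs, 1), sample(overhangs, 1),
                      core_len = sample(15:40, 1)))
    got <- product_canon(ligate_products(frags))
    want <- oracle_circles(frags)
    expect_identical(got, want)
  }
})

test_that("product nucleotide count equals the sum of its fragments", {
  set.seed(64)
  f1 <- random_fragment("ACC", "ATT", core_len = 25)
  f2 <- random_fragment("AAT", "GGT", core_len = 31)
  prods <- ligate_products(list(f1, f2))
  two_part <- Filter(function(p) nrow(p$part_order) == 2L, prods)
  expect_true(length(two_part) >= 1L)
  for (p in two_part) {
    expect_identical(dna_length(p$molecule),
                     sum(p$part_order$size))
    expect_identical(nrow(p$part_order), length(p$junctions))
  }
})

test_that("a one-pot transfer yields exactly the insert-in-backbone product", {
  lib <- random_element_library(1, seed = 71)
  entry <- make_entry_clone(lib$molecules$E01, tnt_registry,
                            backbone_length = 250L)
  dest <- make_member_plasmid("alpha1A", tnt_registry,
                              backbone_length = 300L)
  pot <- one_pot(list(entry, dest), "EarI")
  expect_length(pot$products, 1L)
  p <- pot$products[[1]]
  expect_true(p$stable)
  prov <- tntsim:::product_provenance(p$molecule)
  expect_identical(prov$id, "E01")
  # re-ligated inputs are enumerated but excluded from the stable set
  expect_true(any(pot$summary$religated_input))
  expect_false(any(pot$summary$religated_input &
                     pot$summary$stable))
})

test_that("three entries chain through signatures 3 and 4 in input order", {
  lib <- random_element_library(3, seed = 72)
  mk <- function(id, member) {
    entry <- make_entry_clone(lib$molecules[[id]], tnt_registry,
                              backbone_length = 250L)
    dest <- make_member_plasmid(member, tnt_registry,
                                backbone_length = 300L)
    erase_marks(one_pot(list(entry, dest), "EarI")$products[[1]]$molecule)
  }
  a <- mk("E01", "alpha1A")
  b <- mk("E02", "alphaB")
  cc <- mk("E03", "alphaC")
  dest <- make_member_plasmid("omega1A", tnt_registry,
                              backbone_length = 300L)
  pot <- one_pot(list(a, b, cc, dest), "LguI")
  expect_length(pot$products, 1L)
  prov <- tntsim:::product_provenance(pot$products[[1]]$molecule)
  expect_identical(prov$id, c("E01", "E02", "E03"))

  # omitting the middle entry leaves no closed product and names the
  # dangling junctions (signatures 3 and 4)
  pot2 <- one_pot(list(a, cc, dest), "LguI")
  expect_length(pot2$products, 0L)
  sigs <- attr(tnt_registry, "signatures")
  expect_setequal(pot2$dangling, c(sigs$s3, sigs$s4))
})

test_that("one-pot output is invariant to input ordering", {
  lib <- random_element_library(1, seed = 73)
  entry <- make_entry_clone(lib$molecules$E01, tnt_registry,
                            backbone_length = 250L)
  dest <- make_member_plasmid("omega2", tnt_registry,
                              backbone_length = 300L)
  p1 <- one_pot(list(entry, dest), "LguI")$products
  p2 <- one_pot(list(dest, entry), "LguI")$products
  expect_identical(product_canon(p1), product_canon(p2))
})

test_that("ORF continuity requires whole-codon spans and no internal stop", {
  # two stop-free CDS parts joined through one 3-nt junction
  mol <- dna_molecule("orf", paste0("ATGGCTGCA", "GAT", "GCAGCTTGA"))
  res <- check_orf_continuity(mol, tibble::tibble(start = c(0L, 12L),
                                                  end = c(9L, 21L)))
  expect_true(res$ok)
  # a span of length 1 mod 3 reports the frameshift position
  res2 <- check_orf_continuity(mol, tibble::tibble(start = c(0L, 13L),
                                                   end = c(10L, 21L)))
  expect_false(res2$ok)
  expect_identical(res2$report$frameshift_at[1], 10L)
  # single span, no junction
  res3 <- check_orf_continuity(mol, tibble::tibble(start = 0L, end = 9L))
  expect_true(res3$ok)
  # internal stop fails
  stopmol <- dna_molecule("s", "ATGTAAGCATGA")
  res4 <- check_orf_continuity(stopmol,
                               tibble::tibble(start = 0L, end = 12L))
  expect_false(res4$ok)
  expect_true(res4$internal_stop)
  expect_error(check_orf_continuity(mol, tibble::tibble(start = 0L,
                                                        end = 99L)),
               "outside")
})
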