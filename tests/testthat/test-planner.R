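test_that("plan depth matches the ternary combination arithmetic", {
  expect_identical(plan_assembly(as.character(1:27))$total_steps, 4L)
  expect_identical(plan_assembly(as.character(1:28))$total_steps, 5L)
  expect_identical(plan_assembly(as.character(1:3))$total_steps, 2L)
  expect_identical(plan_assembly("one")$total_steps, 1L)
  for (n in 2:100) {
    expect_identical(plan_assembly(as.character(seq_len(n)))$total_steps,
                     1L + as.integer(ceiling(log(n, 3))),
                     info = paste("n =", n))
  }
  expect_error(plan_assembly(character()), "at least one")
  expect_error(plan_assembly(c("a", "a")), "unique")
})

test_that("families strictly alternate across levels", {
  pl <- plan_assembly(as.character(1:20), first_family = "omega")
  fam <- sub("(1A|2|B|C).*$", "", pl$steps$destination)
  for (lv in unique(pl$steps$level)) {
    fams <- unique(fam[pl$steps$level == lv])
    expect_length(fams, 1L)
    expect_identical(fams, if (lv %% 2 == 1) "omega" else "alpha")
  }
})

test_that("group sizes avoid internal singletons and use 1A/2 or 1A/B/C", {
  pl <- plan_assembly(as.character(1:28))
  sizes <- vapply(pl$steps$inputs[pl$steps$level > 1],
                  length, integer(1))
  expect_true(all(sizes %in% c(2L, 3L)))
  combin <- pl$steps[pl$steps$level == 2L, ]
  expect_identical(sum(vapply(combin$inputs, length, integer(1)) == 3L), 8L)
  expect_identical(sum(vapply(combin$inputs, length, integer(1)) == 2L), 2L)
})

test_that("plan tidiers report rounds and reaction mix", {
  pl <- plan_assembly(as.character(1:9))
  td <- tidy(pl)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 9L + 3L + 1L)
  gl <- glance(pl)
  expect_identical(gl$total_steps, 3L)
  expect_identical(gl$n_ternary, 4L)
  plt <- ggplot2::autoplot(pl)
  expect_s3_class(plt, "ggplot")
})

test_that("simulated plans reproduce order and orientation end-to-end", {
  lib <- random_element_library(8, seed = 91, min_len = 60, max_len = 140)
  ids <- names(lib$molecules)
  cache <- new.env(parent = emptyenv())
  set.seed(92)
  for (rep in 1:6) {
    n <- sample(1:8, 1)
    sel <- sample(ids, n)
    ori <- sample(c("sense", "antisense"), n, replace = TRUE)
    pl <- plan_assembly(tibble::tibble(id = sel, orientation = ori))
    sim <- simulate_plan(pl, lib, tnt_registry, backbone_length = 250L,
                         cache = cache)
    expect_identical(sim$provenance$id, sel)
    expect_identical(sim$provenance$orientation, ori)
  }
})

test_that("an antisense element appears reverse-complemented in the product", {
  lib <- random_element_library(2, seed = 93)
  pl <- plan_assembly(tibble::tibble(id = c("E01", "E02"),
                                     orientation = c("sense",
                                                     "antisense")))
  sim <- simulate_plan(pl, lib, tnt_registry, backbone_length = 250L)
  seqs <- sim$construct$sequence
  e2 <- lib$molecules$E02$sequence
  doubled <- paste0(seqs, seqs)
  expect_true(grepl(oracle_rc(e2), doubled, fixed = TRUE))
  expect_false(grepl(e2, doubled, fixed = TRUE))
})

test_that("predicted insert sizes match the simulated sequences exactly", {
  lib <- random_element_library(5, seed = 94, min_len = 60, max_len = 140)
  pl <- plan_assembly(names(lib$molecules))
  sim <- simulate_plan(pl, lib, tnt_registry, backbone_length = 250L)
  pred <- insert_size(pl, lib, tnt_registry)
  # release span of every construct equals the footprint of the fragment
  # its member actually releases
  for (si in seq_len(nrow(pl$steps))) {
    node <- pl$steps$output[si]
    constr <- sim$constructs[[node]]
    member <- pl$steps$destination[si]
    enz <- tnt_registry$release_enzyme[tnt_registry$name == member]
    if (enz == "EarI+LguI") enz <- "EarI"
    rel <- digest(constr, enz)
    ins <- Filter(function(f) any(f$features$type == "element"), rel)
    expect_length(ins, 1L)
    expect_identical(as.integer(pred$release_span[pred$node == node]),
                     tntsim:::fragment_span(ins[[1]]))
  }
})

test_that("joining 3.9/4.0/4.1 kb sub-inserts predicts a 12 kb insert", {
  # element lengths chosen so the three level-1 release spans are 3.9,
  # 4.0 and 4.1 kb (members 1A/B/C add 9, 12 and 9 nt of junction
  # bookkeeping); the ternary join then merges one shared 3-mer per
  # junction
  mk <- function(id, len) dna_molecule(id, strrep("ACGGATTC",
                                                  ceiling(len / 8)) |>
                                         substr(1, len))
  lib <- list(A = mk("A", 3891L), B = mk("B", 3988L), C = mk("C", 4091L))
  pl <- plan_assembly(c("A", "B", "C"))
  sz <- insert_size(pl, lib, tnt_registry)
  expect_identical(as.integer(sz$release_span[sz$level == 1]),
                   c(3900L, 4000L, 4100L))
  final <- sz$insert_span[sz$level == 2]
  expect_identical(round(final / 1000), 12)
})

test_that("a plan can finish in the entry vector for library re-entry", {
  lib <- random_element_library(2, seed = 95)
  pl <- plan_assembly(c("E01", "E02"), final_destination = "pSTART")
  expect_identical(pl$final_family, "entry")
  sim <- simulate_plan(pl, lib, tnt_registry, backbone_length = 250L)
  expect_identical(sim$provenance$id, c("E01", "E02"))
  # the result is a true library entry: it releases with either enzyme
  rel <- digest(sim$construct, "LguI")
  expect_true(length(rel) >= 2L)
})
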