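test_that("classify_form applies the S/L cutoffs with an ambiguous band", {
  expect_identical(classify_form(280), "S")
  expect_identical(classify_form(942), "L")
  expect_identical(classify_form(500), "AMBIGUOUS")
  expect_identical(classify_form(425), "S")   # oversized short-like candidates
  expect_identical(classify_form(600), "L")
  expect_error(classify_form(0), "positive")
})

test_that("delineate_arm recovers planted arm type and length", {
  p <- synth_protein(protein_spec("TM_S", seed = 21))
  chain <- find_motif_chain(p$sequence, architecture = "TM_S")
  arm <- delineate_arm(chain, p$sequence)
  expect_identical(arm$arm_type, "TM")
  expect_equal(arm$length, 30L)
  expect_true(arm$has_kl)
  expect_false(arm$has_gp)
  expect_equal(c(arm$start, arm$end), p$truth$arm)

  pb <- synth_protein(protein_spec("BACTERIAL_S", seed = 22))
  chb <- find_motif_chain(pb$sequence, architecture = "BACTERIAL_S")
  armb <- delineate_arm(chb, pb$sequence)
  expect_identical(armb$arm_type, "BACTERIAL")
  expect_equal(armb$length, 55L)
  expect_true(armb$has_gp)
})

test_that("delineate_arm flags chains without anchors", {
  chain <- find_motif_chain(strrep("A", 100), architecture = "TM_S")
  arm <- delineate_arm(chain, strrep("A", 100))
  expect_identical(arm$arm_type, "NONE")
  expect_equal(arm$length, 0L)
  expect_true(arm$flagged)
})

test_that("split_halves lands on the planted duplication junction", {
  for (seed in 31:35) {
    p <- synth_protein(protein_spec("EUKARYOTIC_L", seed = seed))
    hs <- split_halves(p$sequence)
    expect_lte(abs(hs$split_index - p$truth$junction), 10L)
    expect_true(hs$c_half_chain$complete)
    expect_true(hs$n_half_chain$complete)
    # chains lie strictly within their halves
    expect_true(all(hs$n_half_chain$hits$end <= hs$split_index))
    expect_true(all(hs$c_half_chain$hits$start >= hs$split_index))
  }
})

test_that("split_halves falls back to the midpoint on featureless input", {
  hs <- split_halves(strrep("A", 700))
  expect_equal(hs$split_index, 350L)
  expect_equal(nrow(hs$c_half_chain$hits), 0L)
  # the pseudo Motif I anchor ("xxDx" required to differ at the Asp) is
  # satisfiable by design on any D-free window; nothing else may hit
  expect_true(all(hs$n_half_chain$hits$motif == "PSEUDO_I"))
  expect_false(hs$n_half_chain$complete)
  expect_false(hs$c_half_chain$complete)
})

test_that("two concatenated short TM-type proteins do not pass as a long form", {
  p1 <- synth_protein(protein_spec("TM_S", seed = 41))
  p2 <- synth_protein(protein_spec("TM_S", seed = 42))
  seq2 <- paste0(p1$sequence, p2$sequence)
  hs <- split_halves(seq2)
  # the TM architecture lacks PxKxRN and HST, so no half satisfies the full
  # long-form catalytic architecture, and the pseudo-architecture (needing a
  # GP arm) fails in the N-half
  expect_false(hs$c_half_chain$complete)
  expect_false(hs$n_half_chain$complete)
  r <- classify_type(seq2)
  expect_identical(r$ztype, "TLP_L")
})

test_that("classify_type recovers each planted type", {
  r <- classify_type(synth_protein(protein_spec("TM_S", seed = 51))$sequence)
  expect_identical(c(r$form, r$ztype), c("S", "TM_S"))
  r <- classify_type(synth_protein(protein_spec("BACTERIAL_S", seed = 52))$sequence)
  expect_identical(c(r$form, r$ztype), c("S", "BACTERIAL_S"))
  r <- classify_type(synth_protein(protein_spec("EUKARYOTIC_L", seed = 53))$sequence)
  expect_identical(c(r$form, r$ztype), c("L", "EUKARYOTIC_L"))
  expect_error(classify_type(""), "non-empty")
})

test_that("mutating the second His of the His motif yields a TLP", {
  # analogue of the natural TLP in which His2 of HxHxDH is mutated to Gln
  p <- synth_protein(protein_spec("BACTERIAL_S", seed = 61))
  m2 <- p$truth$motifs[p$truth$motifs$name == "MOTIF_II", ]
  chars <- strsplit(p$sequence, "")[[1L]]
  expect_identical(chars[m2$start + 3L], "H")
  chars[m2$start + 3L] <- "Q"
  r <- classify_type(paste(chars, collapse = ""))
  expect_identical(r$ztype, "TLP_S")
  expect_true("MOTIF_II" %in% r$missing_required)
})

test_that("knockouts are reported with their exact missing-motif sets", {
  sets <- list(TM_S = c("KL"), TM_S = c("EGXSXXG", "HXH"),
               BACTERIAL_S = c("HEAT"), BACTERIAL_S = c("MOTIF_V"),
               BACTERIAL_S = c("GP", "HST"))
  for (i in seq_along(sets)) {
    base <- names(sets)[i]
    p <- synth_protein(protein_spec(base, knockouts = sets[[i]], seed = 70 + i))
    r <- classify_type(p$sequence)
    expect_identical(r$ztype, "TLP_S")
    expect_setequal(r$missing_required, sets[[i]])
  }
  p <- synth_protein(protein_spec("EUKARYOTIC_L", knockouts = "HEAT", seed = 80))
  r <- classify_type(p$sequence)
  expect_identical(r$ztype, "TLP_L")
  expect_true("HEAT" %in% r$missing_required)
})

test_that("knocking out additional motifs never un-TLPs a protein", {
  base <- protein_spec("BACTERIAL_S", seed = 90)
  p0 <- synth_protein(base)
  req <- trz_catalog()$architectures$BACTERIAL_S$required
  prev_missing <- character()
  cur <- list(sequence = p0$sequence, truth = p0$truth)
  for (ko in c("HEAT", "GP", "MOTIF_II")) {
    cur <- mutate_to_tlp(cur$sequence, cur$truth, ko)
    r <- classify_type(cur$sequence)
    expect_identical(r$ztype, "TLP_S")
    expect_true(all(prev_missing %in% r$missing_required))
    prev_missing <- r$missing_required
  }
})

test_that("arm typing is exclusive and typing results satisfy form invariants", {
  s <- synth_protein_set(n_per_type = 3, seed = 123)
  typing <- trz_classify(s$sequences)
  for (r in attr(typing, "results")) {
    arm <- r$arm
    if (arm$arm_type == "TM") expect_true(arm$has_kl && !arm$has_gp)
    if (arm$arm_type %in% c("BACTERIAL", "EUKARYOTIC")) expect_true(arm$has_gp)
    if (r$ztype %in% c("TM_S", "BACTERIAL_S")) expect_identical(r$form, "S")
    if (r$ztype == "EUKARYOTIC_L") expect_identical(r$form, "L")
    if (r$ztype %in% c("TLP_S", "TLP_L"))
      expect_gt(length(r$missing_required), 0L)
  }
})
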