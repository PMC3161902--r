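test_that("compile_motif parses consensus notation token by token", {
  m <- compile_motif("HxHxDH", 0)
  expect_length(m$positions, 6L)
  expect_identical(m$positions[[1L]], "H")
  expect_null(m$positions[[2L]])
  expect_identical(m$positions[[5L]], "D")
  expect_identical(format_motif(m), "HxHxDH")

  expect_length(compile_motif("x", 0)$positions, 1L)
  expect_null(compile_motif("x", 0)$positions[[1L]])

  m2 <- compile_motif("Px[KL]xRN", 0)
  expect_length(m2$positions, 6L)
  expect_setequal(m2$positions[[3L]], c("K", "L"))
  expect_identical(format_motif(m2), "Px[KL]xRN")
})

test_that("compile_motif round-trips random patterns through the formatter", {
  set.seed(11)
  for (i in 1:50) {
    pat <- random_pattern(sample(3:10, 1L))
    m <- compile_motif(pat, 0)
    m2 <- compile_motif(format_motif(m), 0)
    expect_identical(m$positions, m2$positions)
  }
})

test_that("compile_motif rejects malformed patterns, naming the offending index", {
  expect_error(compile_motif("HxB", 0), "illegal character 'B' at index 3")
  expect_error(compile_motif("H[KL", 0), "unbalanced bracket opened at index 2")
  expect_error(compile_motif("H[]L", 0), "empty bracket")
  expect_error(compile_motif("", 0), "non-empty")
  expect_error(compile_motif("HxH", 3), "max_mismatches")
  expect_error(compile_motif("HxH", -1), "max_mismatches")
})

test_that("scan_motif finds planted consensus instances", {
  h <- scan_motif("AAHSHLDHAA", compile_motif("HxHxDH", 0, name = "MOTIF_II"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 2L)
  expect_equal(h$end, 8L)
  expect_identical(h$matched, "HSHLDH")
  expect_equal(h$mismatches, 0L)

  h2 <- scan_motif("MGAPAGPK", compile_motif("GxPxGP", 0, name = "GP"))
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$start, 1L)
  expect_identical(h2$matched, "GAPAGP")

  # one substitution tolerated at max_mismatches 1
  h3 <- scan_motif("AAHSHLEHAA", compile_motif("HxHxDH", 1, name = "MOTIF_II"))
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$start, 2L)
  expect_equal(h3$mismatches, 1L)
})

test_that("scan_motif handles degenerate inputs", {
  m <- compile_motif("HxHxDH", 0)
  expect_equal(nrow(scan_motif("", m)), 0L)
  expect_equal(nrow(scan_motif("HXH", m)), 0L)        # shorter than pattern
  # unknown residue X matches only wildcards
  expect_equal(nrow(scan_motif("HXHXDH", m)), 1L)
  expect_equal(nrow(scan_motif("XSHLDH", m)), 0L)
})

test_that("scan_motif equals brute-force window enumeration on random cases", {
  set.seed(42)
  for (i in 1:200) {
    pat <- random_pattern(sample(3:8, 1L))
    plen <- length(compile_motif(pat, 0)$positions)
    m <- compile_motif(pat, min(sample(0:2, 1L), plen - 1L), name = "P")
    s <- random_protein(sample(5:60, 1L))
    got <- scan_motif(s, m)
    want <- brute_scan(s, pat, m$max_mismatches)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("raising max_mismatches never reduces the number of hits", {
  set.seed(7)
  for (i in 1:60) {
    pat <- random_pattern(sample(4:8, 1L))
    s <- random_protein(sample(20:60, 1L))
    n_prev <- -1L
    plen <- length(compile_motif(pat, 0)$positions)
    for (mm in 0:min(3L, plen - 1L)) {
      n <- nrow(scan_motif(s, compile_motif(pat, mm, name = "P")))
      expect_gte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("find_motif_chain recovers all planted motif coordinates exactly", {
  for (seed in 1:5) {
    p <- synth_protein(protein_spec("TM_S", seed = seed))
    chain <- find_motif_chain(p$sequence, architecture = "TM_S")
    expect_true(chain$complete)
    expect_sound_chain(chain)
    truth <- p$truth$motifs[order(p$truth$motifs$start), ]
    expect_identical(chain$hits$motif, truth$name)
    expect_identical(chain$hits$start, truth$start)
    expect_identical(chain$hits$end, truth$end)
    expect_true(all(chain$hits$mismatches == 0L))
  }
  for (seed in 1:5) {
    p <- synth_protein(protein_spec("BACTERIAL_S", seed = seed))
    chain <- find_motif_chain(p$sequence, architecture = "BACTERIAL_S")
    expect_true(chain$complete)
    truth <- p$truth$motifs[order(p$truth$motifs$start), ]
    expect_identical(chain$hits$start, truth$start)
  }
})

test_that("a featureless sequence yields an empty, incomplete chain", {
  chain <- find_motif_chain(strrep("A", 200), architecture = "TM_S")
  expect_equal(nrow(chain$hits), 0L)
  expect_false(chain$complete)
  expect_setequal(chain$missing_required,
                  trz_catalog()$architectures$TM_S$required)
})

test_that("a His-motif knockout leaves exactly MOTIF_II missing", {
  p <- synth_protein(protein_spec("TM_S", knockouts = "MOTIF_II", seed = 9))
  chain <- find_motif_chain(p$sequence, architecture = "TM_S")
  expect_false(chain$complete)
  expect_identical(chain$missing_required, "MOTIF_II")
})

test_that("chains are sound for every architecture on arbitrary sequences", {
  set.seed(13)
  cat <- trz_catalog()
  for (i in 1:10) {
    s <- random_protein(sample(100:400, 1L))
    for (arch in names(cat$architectures))
      expect_sound_chain(find_motif_chain(s, cat, arch))
  }
})

test_that("the catalog round-trips through its plain-text file format", {
  cat <- trz_catalog()
  path <- tempfile(fileext = ".txt")
  write_catalog(cat, path)
  cat2 <- read_catalog(path)
  expect_identical(names(cat2$entries), names(cat$entries))
  for (nm in names(cat$entries)) {
    expect_identical(format_motif(cat2$entries[[nm]]), format_motif(cat$entries[[nm]]))
    expect_identical(cat2$entries[[nm]]$max_mismatches, cat$entries[[nm]]$max_mismatches)
    expect_identical(cat2$entries[[nm]]$rank, cat$entries[[nm]]$rank)
    expect_identical(cat2$entries[[nm]]$require_mismatch, cat$entries[[nm]]$require_mismatch)
  }
  expect_identical(cat2$architectures, cat$architectures)
})
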