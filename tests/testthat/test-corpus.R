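# Corpus construction: ligand location, window extraction, labeling,
# deduplication, trimming

test_that("peptides are located at their first exact occurrence", {
  expect_identical(locatePeptide("MAAALKSSA", "ALK"), 3L)
  expect_identical(locatePeptide("MAAALKSSA", "QQQ"), NA_integer_)
  expect_warning(off <- locatePeptide("ABCABC", "ABC"), "2 times")
  expect_identical(off, 0L)
})

test_that("window extraction follows the +/-halfWidth span rule", {
  prot <- paste(rep(LETTERS[1:10], 3), collapse = "")  # length 30
  # 0-based indices 12..17 around the bond after index 14
  expect_identical(extractWindow(prot, 14L, 3L),
                   substr(prot, 13, 18))
  expect_identical(nchar(extractWindow(strrep("A", 40), 20L, 14L)), 28L)
  # insufficient context on either side
  expect_identical(extractWindow(strrep("A", 30), 4L, 14L),
                   NA_character_)
  expect_identical(extractWindow(strrep("A", 30), 28L, 14L),
                   NA_character_)
  expect_error(extractWindow("AAAA", 4L, 2L), "out of bounds")
  expect_error(extractWindow("AAAA", -1L, 2L), "out of bounds")
})

test_that("cleavage and non-cleavage P1 indices follow the conventions", {
  # C-terminus of the ligand is P1
  expect_identical(cleavageSiteOf(3L, 9L), 11L)
  expect_identical(cleavageSiteOf(0L, 1L), 0L)
  expect_identical(cleavageSiteOf(100L, 11L), 110L)
  # middle residue (ceiling(L/2)-th) is P1 for the negative site
  expect_identical(noncleavageSiteOf(0L, 9L), 4L)   # 5th residue
  expect_identical(noncleavageSiteOf(0L, 8L), 3L)   # 4th residue
  expect_identical(noncleavageSiteOf(0L, 1L), 0L)
  expect_identical(noncleavageSiteOf(7L, 9L), 11L)
})

test_that("buildSampleSet emits one cleavage and one non-cleavage sample per locatable ligand", {
  set.seed(2)
  prot <- c(p1 = paste(sample(canonicalResidues(), 60, replace = TRUE),
                       collapse = ""))
  lig <- data.frame(peptide = substr(prot[[1]], 33, 41),  # ends 0-based 40
                    source_id = "p1")
  ss <- buildSampleSet(prot, lig, halfWidth = 14L)
  expect_s4_class(ss, "CleavageSampleSet")
  expect_identical(length(ss), 2L)
  expect_setequal(sampleLabels(ss), c("cleavage", "non_cleavage"))
  df <- as.data.frame(sampleInfo(ss))
  cle <- df[df$label == "cleavage", ]
  expect_identical(cle$siteIndex, 40L)
  expect_identical(nchar(cle$window), 28L)
  # reconstruction: the window is the protein substring at the site
  expect_identical(cle$window, substr(prot[[1]], 40 - 14 + 2, 40 + 15))
})

test_that("records without full context or source are dropped with reasons", {
  set.seed(2)
  prot <- c(p1 = paste(sample(canonicalResidues(), 60, replace = TRUE),
                       collapse = ""))
  # ligand ends too close to the C-terminus: the cleavage-side window
  # lacks downstream context but the interior non-cleavage site survives
  lig <- data.frame(peptide = substr(prot[[1]], 41, 49),  # offset 40
                    source_id = "p1")
  ss <- buildSampleSet(prot, lig, halfWidth = 14L)
  expect_identical(sampleLabels(ss), "non_cleavage")
  expect_identical(unname(dropStats(ss)["insufficient_context"]), 1L)
  # unlocatable ligand
  ss2 <- buildSampleSet(prot, data.frame(peptide = "WWWWWWWWWW",
                                         source_id = "p1"),
                        halfWidth = 14L)
  expect_identical(length(ss2), 0L)
  expect_identical(unname(dropStats(ss2)["peptide_not_found"]), 2L)
  # unknown source id
  ss3 <- buildSampleSet(prot, data.frame(peptide = "ACD",
                                         source_id = "nope"),
                        halfWidth = 14L)
  expect_identical(length(ss3), 0L)
})

test_that("duplicate (window, label) pairs collapse and conflicts keep the cleavage copy", {
  set.seed(2)
  prot <- c(p1 = paste(sample(canonicalResidues(), 60, replace = TRUE),
                       collapse = ""))
  lig <- data.frame(peptide = rep(substr(prot[[1]], 33, 41), 2),
                    source_id = "p1")
  ss <- buildSampleSet(prot, lig, halfWidth = 14L)
  expect_identical(length(ss), 2L)
  expect_identical(unname(dropStats(ss)["duplicate_window"]), 2L)
  # engineered conflict: in a homopolymer every 28-residue window is the
  # same string, so a non-cleavage window collides with a cleavage one
  prot2 <- c(h = strrep("A", 80))
  lig2 <- data.frame(peptide = c(strrep("A", 20), strrep("A", 30)),
                     source_id = "h")
  ss2 <- buildSampleSet(prot2, lig2, halfWidth = 14L)
  expect_identical(sampleLabels(ss2), "cleavage")
  expect_gte(unname(dropStats(ss2)["label_conflict"]), 1L)
})

test_that("non-canonical residues in a window drop the sample", {
  prot <- c(p1 = "ACDEFXHIKLMNP")  # X at 0-based index 5
  lig <- data.frame(peptide = "CDEFXH", source_id = "p1")
  ss <- buildSampleSet(prot, lig, halfWidth = 3L)
  expect_identical(length(ss), 0L)
  expect_identical(unname(dropStats(ss)["non_canonical_residue"]), 2L)
})

test_that("empty inputs yield an empty sample set with stats", {
  ss <- buildSampleSet(character(), data.frame(peptide = character(),
                                               source_id = character()),
                       halfWidth = 10L)
  expect_identical(length(ss), 0L)
  expect_true(all(dropStats(ss) == 0L))
})

test_that("windows have even length with P1 at 0-based index halfWidth-1", {
  cfg <- smallSimConfig()
  pro <- generateProteome(cfg)
  pl <- plantCleavages(pro, cfg)
  for (h in c(6L, 10L, 14L)) {
    ss <- buildSampleSet(pro, pl$ligands, halfWidth = h)
    df <- as.data.frame(sampleInfo(ss))
    expect_true(all(nchar(df$window) == 2L * h))
    # reconstruction + P1 placement: window[halfWidth] is the protein's
    # residue at siteIndex
    p1InWin <- substr(df$window, h, h)
    p1InProt <- substr(pro[df$sourceId], df$siteIndex + 1L,
                       df$siteIndex + 1L)
    expect_identical(p1InWin, unname(p1InProt))
    expect_lte(sum(df$label == "cleavage"), nrow(pl$ligands))
    expect_lte(sum(df$label == "non_cleavage"), nrow(pl$ligands))
  }
})

test_that("trimming is symmetric, composable, and re-deduplicates", {
  cfg <- smallSimConfig()
  pro <- generateProteome(cfg)
  pl <- plantCleavages(pro, cfg)
  ss14 <- buildSampleSet(pro, pl$ligands, halfWidth = 14L)
  ss10 <- trimSamples(ss14, 10L)
  expect_identical(ss10@halfWidth, 10L)
  expect_true(all(nchar(sampleWindows(ss10)) == 20L))
  # a trimmed window sits centered inside its parent
  expect_identical(sampleWindows(ss10)[1],
                   substr(sampleWindows(ss14)[1], 5, 24))
  # composition trim(trim(S,a),b) == trim(S,b)
  ssAB <- trimSamples(trimSamples(ss14, 12L), 8L)
  ssB <- trimSamples(ss14, 8L)
  expect_identical(sort(paste(sampleWindows(ssAB), sampleLabels(ssAB))),
                   sort(paste(sampleWindows(ssB), sampleLabels(ssB))))
  # identity trim
  expect_identical(sampleWindows(trimSamples(ss14, 14L)),
                   sampleWindows(ss14))
  expect_error(trimSamples(ss10, 14L), "1\\.\\.halfWidth")
  # engineered collapse: two cleavage windows distinct only in their
  # outer flanks become identical after trimming
  prot <- c(a = paste0("WYYY", strrep("A", 44)),
            b = paste0("MHHH", strrep("A", 44)))
  lig <- data.frame(peptide = strrep("A", 12), source_id = c("a", "b"))
  sA <- buildSampleSet(prot, lig, halfWidth = 14L)
  expect_identical(length(sA), 2L)
  expect_identical(length(unique(sampleWindows(sA))), 2L)
  sB <- trimSamples(sA, 10L)
  expect_identical(length(sB), 1L)
})

test_that("samples TSV round-trips through write/read", {
  prot <- fixtureProteins()
  ss <- buildSampleSet(prot, fixtureLigands(), halfWidth = 10L)
  expect_identical(unname(dropStats(ss)["peptide_not_found"]), 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  dl <- withr::local_tempfile(fileext = ".tsv")
  writeSamples(ss, f, dropLogPath = dl)
  back <- readSamples(f)
  expect_identical(sampleWindows(back), sampleWindows(ss))
  expect_identical(sampleLabels(back), sampleLabels(ss))
  expect_identical(back@halfWidth, ss@halfWidth)
  log <- read.table(dl, header = TRUE, sep = "\t", quote = "")
  expect_identical(log$count[log$reason == "peptide_not_found"], 2L)
})
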