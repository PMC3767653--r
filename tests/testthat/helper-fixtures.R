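# Shared in-code fixtures: a tiny deterministic protein/ligand corpus
# and a small planted-rule simulation reused across test files.

fixtureProteins <- function() {
  c(protA = paste0("MKLVFFAEDVGSNKGAIIGLMVGGVVIATVIVITLVML",
                   "RRKQEMSVDELSARLQGEAKTR"),
    protB = "MAAALKSSAWWFLKHPETNAAGQRSTVYLMKE")
}

fixtureLigands <- function() {
  data.frame(
    peptide = c("GSNKGAIIG",   # 9-mer inside protA
                "AWWFLKHPE",   # 9-mer inside protB
                "NOTTHERE"),   # unlocatable
    source_id = c("protA", "protB", "protA"),
    stringsAsFactors = FALSE)
}

# small, quickly separable planted-rule configuration
smallSimConfig <- function(seed = 101L, ...) {
  simulationConfig(nProteins = 15L, proteinLength = 100L,
                   nLigands = 150L, seed = seed, ...)
}

# fit a small linear model on a planted-rule corpus; memoized per session
fixtureLinearModel <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- smallSimConfig()
    pro <- generateProteome(cfg)
    pl <- plantCleavages(pro, cfg)
    ss <- buildSampleSet(pro, pl$ligands, halfWidth = 10L)
    raw <- encodeSamples(ss)
    sc <- fitScaler(raw)
    m <- trainSvm(applyScaler(sc, raw), kernel = "linear", C = 1,
                  scaler = sc)
    cache <<- list(model = m, sampleSet = ss, raw = raw, scaler = sc)
    cache
  }
})

# hand-built profile: unit hydrophobic weight at P1, -1 at P1', zeros
# elsewhere, identity scaler
unitP1Profile <- function(halfWidth = 10L, selection = c(1L, 3L, 5L)) {
  pos <- positionLabels(halfWidth)
  w <- matrix(0, nrow = length(pos), ncol = length(selection),
              dimnames = list(pos, paste0("VHSE", selection)))
  w["P1", "VHSE1"] <- 1
  w["P1'", "VHSE1"] <- -1
  methods::new("PositionWeightProfile", weights = w,
               halfWidth = as.integer(halfWidth),
               selection = as.integer(selection), scaler = list())
}
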