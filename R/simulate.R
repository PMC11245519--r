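# Synthetic-data generators: planted-motif sequence cohorts with ground
# truth, one-site ITC titrations, and two-state melt curves.  Every
# generator is a pure function of (config, seed).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Background residue composition presets
#'
#' @param preset `"uniform"` (all 20 residues equal) or `"dcache"`, a
#'   globular-domain-like composition enriched in small and hydrophobic
#'   residues.
#' @return Named numeric vector of residue frequencies summing to 1.
#' @export
backgroundFrequencies <- function(preset = c("uniform", "dcache")) {
  preset <- match.arg(preset)
  if (preset == "uniform")
    return(setNames(rep(1 / 20, 20), AA20))
  f <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
         I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
         R = 5.5, S = 6.6, T = 5.3, V = 6.9, W = 1.1, Y = 2.9)
  f / sum(f)
}

#' Configure a planted-motif cohort
#'
#' @param nPositives,nDecoys Number of motif-bearing and background
#'   sequences.
#' @param motif A [MotifDefinition] to plant (default [purineMotif()]).
#' @param variantWeights Named probabilities of motif variant strings
#'   (5 letters, one per position); default equal weight on the variants
#'   observed among experimentally characterized receptors.
#' @param spacingJitter Maximum absolute offset applied to each spacing
#'   (clipped to the motif windows); default 2.
#' @param background Residue frequency vector
#'   ([backgroundFrequencies()]).
#' @param domainLength Length range of generated sequences (default
#'   180-220, the size of a dCache_1 sensor domain region).
#' @param taxonomyPool,architecturePool Character vectors of lineage /
#'   architecture labels sampled uniformly for the annotation table.
#' @return A validated config list.
#' @export
cohortConfig <- function(nPositives = 100L, nDecoys = 1000L,
                         motif = purineMotif(),
                         variantWeights = NULL, spacingJitter = 2L,
                         background = backgroundFrequencies("uniform"),
                         domainLength = c(180L, 220L),
                         taxonomyPool = c(
                           "Bacteria;Pseudomonadota;Gammaproteobacteria",
                           "Bacteria;Bacillota;Clostridia",
                           "Bacteria;Campylobacterota;Campylobacteria",
                           "Bacteria;Actinomycetota;Coriobacteriia",
                           "Bacteria;Verrucomicrobiota;Verrucomicrobiae"),
                         architecturePool = c(
                           "dCache_1|MCPsignal", "dCache_1|GGDEF|EAL",
                           "dCache_1|GGDEF", "dCache_1|HisKA|HATPase_c",
                           "dCache_1|SpoIIE")) {
  if (is.null(variantWeights)) {
    vs <- c("YRWFN", "YKWYN", "YRWFD", "FRFYN", "YKWFN", "YHWFN")
    variantWeights <- setNames(rep(1 / length(vs), length(vs)), vs)
  }
  if (abs(sum(variantWeights) - 1) > 1e-9)
    stop("variant weights must sum to 1")
  k <- length(motif@positionNames)
  badv <- names(variantWeights)[vapply(names(variantWeights), function(v) {
    r <- strsplit(v, "")[[1L]]
    length(r) != k || !all(mapply(`%in%`, r, motif@allowed))
  }, logical(1))]
  if (length(badv))
    stop("variant(s) incompatible with the motif's allowed sets: ",
         paste(badv, collapse = ", "))
  if (nPositives + nDecoys < 1L) stop("empty cohort requested")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  span <- k + sum(motif@spacings$max)
  if (span > min(domainLength))
    stop("motif span (", span, ") cannot fit the domain length range")
  list(nPositives = as.integer(nPositives), nDecoys = as.integer(nDecoys),
       motif = motif, variantWeights = variantWeights,
       spacingJitter = as.integer(spacingJitter), background = background,
       domainLength = as.integer(domainLength),
       taxonomyPool = taxonomyPool, architecturePool = architecturePool)
}

sample_background <- function(len, background) {
  paste0(sample(names(background), len, replace = TRUE,
                prob = background), collapse = "")
}

plant_motif <- function(len, variantRes, motif, jitter, background) {
  sp <- motif@spacings
  gaps <- mapply(function(mn, ce, mx) {
    g <- ce + sample(seq(-jitter, jitter), 1L)
    min(max(g, mn), mx)
  }, sp$min, sp$center, sp$max)
  span <- length(variantRes) + sum(gaps)
  start <- sample(seq_len(len - span + 1L), 1L)
  pos <- start + cumsum(c(0L, gaps + 1L))
  chars <- strsplit(sample_background(len, background), "")[[1L]]
  chars[pos] <- variantRes
  comp <- motif@companion
  if (length(comp)) {
    cpos <- pos[match(comp$anchor, motif@positionNames)] + comp$offset
    chars[cpos] <- sample(comp$allowed, 1L)
  }
  list(seq = paste0(chars, collapse = ""), positions = pos)
}

#' Simulate a planted-motif sequence cohort
#'
#' Positives carry exactly one planted motif instance (variant drawn
#' from the configured weights, spacings jittered within the motif
#' windows) which the linear scanner provably recovers: candidate
#' positives are rejection-sampled until [scanLinear()] reports the
#' planted positions and variant.  Decoys are background sequences
#' rejection-sampled until the scanner finds no match, so specificity
#' checks against them are exact.  Reproducible given `seed`.
#'
#' @param config From [cohortConfig()].
#' @param seed Integer seed.
#' @return A list: `sequences` (`AAStringSet`), `truth` (data.frame
#'   `id`, `positive`, `variant`, `positions` comma-string), and
#'   `annotations` (annotation table layout).
#' @export
simulateCohort <- function(config, seed = 1L) {
  with_seed(seed, {
    motif <- config$motif
    ids <- c(sprintf("POS%04d", seq_len(config$nPositives)),
             sprintf("DEC%04d", seq_len(config$nDecoys)))
    seqs <- character(length(ids))
    variants <- character(length(ids))
    posstr <- character(length(ids))
    lens <- sample(seq(config$domainLength[1L], config$domainLength[2L]),
                   length(ids), replace = TRUE)
    for (i in seq_len(config$nPositives)) {
      v <- sample(names(config$variantWeights), 1L,
                  prob = config$variantWeights)
      vres <- strsplit(v, "")[[1L]]
      repeat {
        pl <- plant_motif(lens[i], vres, motif, config$spacingJitter,
                          config$background)
        sc <- scanLinear(pl$seq, motif)
        if (sc@matched && sc@variant == v &&
            identical(sc@positions, as.integer(pl$positions))) break
      }
      seqs[i] <- pl$seq
      variants[i] <- v
      posstr[i] <- paste(pl$positions, collapse = ",")
    }
    for (i in seq_len(config$nDecoys)) {
      j <- config$nPositives + i
      repeat {
        s <- sample_background(lens[j], config$background)
        if (!scanLinear(s, motif)@matched) break
      }
      seqs[j] <- s
      variants[j] <- "-"
    }
    ss <- Biostrings::AAStringSet(seqs)
    names(ss) <- ids
    ann <- data.frame(
      protein_id = ids,
      lineage = sample(config$taxonomyPool, length(ids), replace = TRUE),
      architecture = sample(config$architecturePool, length(ids),
                            replace = TRUE),
      stringsAsFactors = FALSE)
    list(sequences = ss,
         truth = data.frame(id = ids,
                            positive = seq_along(ids) <= config$nPositives,
                            variant = variants, positions = posstr,
                            stringsAsFactors = FALSE),
         annotations = ann)
  })
}

#' Configure a simulated binding assay
#'
#' Defaults follow the titration protocol used for the wild-type
#' McpH-LBD / adenine measurements (1.4 mL cell, 18 uM protein titrated
#' with 300 uM ligand as one 1.6 uL pre-injection followed by 18 x 12.8
#' uL aliquots) and a two-state melt scanned from 23 to 85 degC in 0.5
#' degC steps.
#'
#' @param trueKd Dissociation constant, mol/L.
#' @param trueDh Binding enthalpy, kcal/mol.
#' @param trueN Stoichiometry.
#' @param cellVolume,cellConc,syringeConc,injectionVolumes ITC protocol
#'   (litres, mol/L).
#' @param dilutionHeat Constant ligand-dilution heat per injection,
#'   microcalories.
#' @param noiseSd Gaussian noise as a fraction of the largest absolute
#'   signal (applied to ITC heats or melt fluorescence).
#' @param trueTm,meltWidth Melt midpoint and transition width, degC.
#' @param meltAmplitude,baselineIntercept,baselineSlope Melt-curve
#'   fluorescence scale and linear baseline.
#' @param temperatureGrid Scan temperatures, degC.
#' @return A config list.
#' @export
assayConfig <- function(trueKd = 2.6e-6, trueDh = -10, trueN = 1,
                        cellVolume = 1.4e-3, cellConc = 18e-6,
                        syringeConc = 300e-6,
                        injectionVolumes = c(1.6e-6, rep(12.8e-6, 18L)),
                        dilutionHeat = -0.5, noiseSd = 0,
                        trueTm = 55, meltWidth = 1.2, meltAmplitude = 100,
                        baselineIntercept = 10, baselineSlope = 0.15,
                        temperatureGrid = seq(23, 85, by = 0.5)) {
  stopifnot(trueKd > 0, trueN > 0, cellVolume > 0, cellConc > 0,
            syringeConc > 0, all(injectionVolumes > 0), noiseSd >= 0,
            meltWidth > 0)
  if (trueTm < min(temperatureGrid) || trueTm > max(temperatureGrid))
    stop("trueTm must lie within the temperature grid")
  as.list(environment())
}

#' Simulate a one-site ITC titration
#'
#' Heats come from the same one-site isotherm the fitter uses, plus a
#' constant dilution heat and i.i.d. Gaussian noise scaled to the
#' largest absolute injection heat.
#'
#' @param config From [assayConfig()].
#' @param seed Integer seed (only used when `noiseSd > 0`).
#' @return A [TitrationSeries] with the exact dilution heats recorded.
#' @export
simulateItc <- function(config, seed = 1L) {
  series <- titrationSeries(config$injectionVolumes,
                            rawHeats = numeric(
                              length(config$injectionVolumes)),
                            cellConc = config$cellConc,
                            syringeConc = config$syringeConc,
                            cellVolume = config$cellVolume,
                            dilutionHeats = rep(
                              config$dilutionHeat,
                              length(config$injectionVolumes)))
  ndh <- one_site_ndh(series, config$trueN, 1 / config$trueKd,
                      config$trueDh)
  heats <- ndh * config$syringeConc * config$injectionVolumes *
    UCAL_PER_KCAL
  noise <- if (config$noiseSd > 0)
    with_seed(seed, rnorm(length(heats), 0,
                          config$noiseSd * max(abs(heats))))
    else numeric(length(heats))
  series@rawHeats <- heats + config$dilutionHeat + noise
  series
}

#' Simulate a two-state melt curve
#'
#' `F(T) = baseline + amplitude / (1 + exp(-(T - Tm)/width)) + noise`
#' on the configured temperature grid.
#'
#' @param config From [assayConfig()].
#' @param seed Integer seed (only used when `noiseSd > 0`).
#' @return A [MeltCurve].
#' @export
simulateMelt <- function(config, seed = 1L) {
  tt <- config$temperatureGrid
  theta <- 1 / (1 + exp(-(tt - config$trueTm) / config$meltWidth))
  ff <- config$baselineIntercept + config$baselineSlope * tt +
    config$meltAmplitude * theta
  if (config$noiseSd > 0)
    ff <- ff + with_seed(seed, rnorm(length(tt), 0,
                                     config$noiseSd *
                                       config$meltAmplitude))
  meltCurve(tt, ff)
}
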