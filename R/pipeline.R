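# End-to-end synthetic study pipeline: landscape -> virtual species ->
# museum sampling -> suitability engines -> cross-engine pseudoabsences ->
# threshold selection -> PDM -> habitat-masked ADM -> simulated field
# survey -> site and buffer validation -> stacked richness.

#' Default scenario configuration
#'
#' The scaled-down synthetic mirror of the study design: a 100 x 100
#' landscape of 6 collinear autocorrelated layers, 3 virtual species with
#' planted marginalities 1.0 / 1.2 / 1.5 (strong habitat selectivity) and
#' intermediate tolerance 0.5, around 100 museum-style records per species
#' (Poisson counts scaled by each species' landscape prevalence, as
#' collection effort scales with range size), a
#' 4-class land cover at a 4x finer grid, and a 46-site point-count survey
#' (30 points per site, 0.2 map-unit spacing) restricted to the species'
#' habitat class.
#'
#' @return named list of scenario parameters.
#' @export
scenarioDefaults <- function() {
  list(n_rows = 100L, n_cols = 100L, n_layers = 6L, autocorr_range = 6,
       n_species = 3L, marginality_targets = c(1.0, 1.2, 1.5),
       tolerance_target = 0.5, n_museum = 100L, clustering = 0,
       n_classes = 4L, patch_scale = 8, subcell_ratio = 4L,
       n_sites = 46L, points_per_site = 30L, min_point_spacing = 0.2,
       detection_prob = 0.8, suitable_classes = 1L, suitable_fraction = 0.5,
       threshold_rule = "kappa", pseudoabsence_threshold = 20,
       buffer_radius = 1.0, n_regions = 4L, train_fraction = 0.75,
       adm_engine = "enfa")
}

mergeConfig <- function(config) {
  cfg <- scenarioDefaults()
  for (k in names(config)) cfg[[k]] <- config[[k]]
  cfg
}

subSeed <- function(seed, i) (as.integer(seed) %% 100000L) * 17L + i * 101L

#' Simulate a complete synthetic scenario
#'
#' Generates the landscape, land cover, habitat table, ecoregions and, per
#' virtual species, the truth suitability, museum-style records and
#' field-survey occurrences, all from one seed.
#'
#' @param seed integer RNG seed.
#' @param config named list overriding [scenarioDefaults()].
#' @return list with \code{stack}, \code{landcover}, \code{habitat},
#'   \code{regions}, \code{species} (per species: \code{vs}, \code{museum},
#'   \code{field}) and the resolved \code{config}.
#' @export
simulateScenario <- function(seed, config = list()) {
  cfg <- mergeConfig(config)
  stack <- genEnvStack(subSeed(seed, 1L), nLayers = cfg$n_layers,
                       nRows = cfg$n_rows, nCols = cfg$n_cols,
                       autocorrRange = cfg$autocorr_range)
  lc <- genLandCover(stack, subSeed(seed, 2L), nClasses = cfg$n_classes,
                     patchScale = cfg$patch_scale,
                     subcellRatio = cfg$subcell_ratio)
  targets <- rep(cfg$marginality_targets, length.out = cfg$n_species)
  speciesNames <- sprintf("virtual_sp%02d", seq_len(cfg$n_species))
  habitat <- HabitatTable(stats::setNames(
    rep(list(as.integer(cfg$suitable_classes)), cfg$n_species), speciesNames))
  species <- lapply(seq_len(cfg$n_species), function(i) {
    vs <- genVirtualSpecies(stack, subSeed(seed, 10L + i),
                            marginalityTarget = targets[i],
                            toleranceTarget = cfg$tolerance_target,
                            species = speciesNames[i],
                            suitableClasses = cfg$suitable_classes)
    # museum effort scales with how widespread the species is, as it does in
    # real collections: expected count ∝ the species' landscape prevalence
    prev <- mean(vs@truth, na.rm = TRUE)
    nMus <- max(3L * cfg$n_layers,
                withSeed(subSeed(seed, 30L + i),
                         stats::rpois(1, cfg$n_museum * prev / 0.05)))
    museum <- sampleOccurrences(vs, nMus, subSeed(seed, 40L + i),
                                clustering = cfg$clustering)
    field <- simulateFieldSurvey(vs, lc, nSites = cfg$n_sites,
                                 pointsPerSite = cfg$points_per_site,
                                 minPointSpacing = cfg$min_point_spacing,
                                 detectionProb = cfg$detection_prob,
                                 seed = subSeed(seed, 70L + i))
    list(vs = vs, museum = museum, field = field)
  })
  list(stack = stack, landcover = lc, habitat = habitat,
       regions = genEcoregions(gridLayout(stack), cfg$n_regions),
       species = species, config = cfg)
}

#' Run the full modeling and validation pipeline on a synthetic scenario
#'
#' For each virtual species: a seeded 75/25 split of the museum records;
#' ENFA and percentile-envelope suitability models fitted on the training
#' points; pseudoabsences for each engine drawn from the *other* engine's
#' preliminary absence area (scores below the configured preliminary
#' threshold), one per test presence; kappa and ROC threshold selection on
#' the default candidate sweep; a PDM from the configured engine and rule;
#' the habitat-masked ADM; and site/buffer validation against the simulated
#' field survey. Thresholds are compared across species per engine with the
#' Wilcoxon signed-rank test, ADMs are stacked into a richness model and
#' cross-tabbed against the synthetic ecoregions.
#'
#' @param seed integer RNG seed.
#' @param config named list overriding [scenarioDefaults()].
#' @param scenario optional pre-built scenario (from [simulateScenario()]);
#'   when supplied, `config` is ignored in favour of the scenario's.
#' @return list with \code{validation} ([ValidationReport]),
#'   \code{thresholds} (per species x engine data.frame),
#'   \code{wilcoxon} (per engine kappa-vs-ROC threshold comparison),
#'   \code{proportionality}, \code{richness}, \code{crosstab},
#'   \code{models} (per-species fitted objects) and \code{scenario}.
#' @export
runScenario <- function(seed, config = list(), scenario = NULL) {
  if (is.null(scenario)) scenario <- simulateScenario(seed, config)
  cfg <- scenario$config
  stack <- scenario$stack
  engines <- c("enfa", "envelope")
  thrRows <- list(); models <- list()
  adms <- list(); fieldSets <- list()
  for (i in seq_along(scenario$species)) {
    sp <- scenario$species[[i]]
    name <- sp$vs@species
    split <- trainTestSplit(sp$museum, cfg$train_fraction, subSeed(seed, 100L + i))
    enfa <- enfaFit(stack, split$train)
    suits <- list(
      enfa = enfaSuitability(enfa, stack, species = name),
      envelope = envelopePredict(stack, split$train, species = name))
    nTest <- length(split$test)
    reports <- list(); pdms <- list()
    for (eng in engines) {
      other <- setdiff(engines, eng)
      prelim <- binarize(suits[[other]], cfg$pseudoabsence_threshold, "external")
      pa <- samplePseudoabsences(prelim, nTest, subSeed(seed, 200L + 10L * i +
                                                          match(eng, engines)),
                                 exclusion = sp$museum, engineUnderTest = eng)
      rep <- metricCurve(suits[[eng]], split$test, pa)
      reports[[eng]] <- rep
      thr <- if (cfg$threshold_rule == "roc") rep@rocThreshold else rep@kappaThreshold
      pdms[[eng]] <- binarize(suits[[eng]], thr, cfg$threshold_rule)
      thrRows[[paste(name, eng)]] <- data.frame(
        species = name, engine = eng, kappaThreshold = rep@kappaThreshold,
        rocThreshold = rep@rocThreshold, auc = rep@auc)
    }
    pdm <- pdms[[cfg$adm_engine]]
    adm <- reduceToAdm(pdm, scenario$landcover, scenario$habitat,
                       species = name,
                       suitableFraction = cfg$suitable_fraction)
    adms[[name]] <- adm
    fieldSets[[name]] <- sp$field
    models[[name]] <- list(enfa = enfa, suitability = suits,
                           reports = reports, pdm = pdm, adm = adm,
                           split = split)
  }
  thresholds <- do.call(rbind, c(thrRows, list(make.row.names = FALSE)))
  wilcox <- lapply(stats::setNames(engines, engines), function(eng) {
    rows <- thresholds[thresholds$engine == eng, ]
    wilcoxonSignedRank(rows$kappaThreshold, rows$rocThreshold)
  })
  validation <- batchValidate(adms, fieldSets, radius = cfg$buffer_radius)
  museumCounts <- vapply(scenario$species, function(s) length(s$museum), 0L)
  fieldCounts <- vapply(scenario$species,
                        function(s) nrow(distinctCells(stack@layout, s$field)), 0L)
  prop <- if (length(museumCounts) >= 3L)
    tryCatch(proportionalityTest(museumCounts, fieldCounts),
             error = function(e) NULL) else NULL
  richness <- stackRichness(unname(adms))
  crosstab <- richnessByRegion(richness, scenario$regions)
  list(validation = validation, thresholds = thresholds, wilcoxon = wilcox,
       proportionality = prop, richness = richness, crosstab = crosstab,
       models = models, scenario = scenario)
}
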