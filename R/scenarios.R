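#' Perturbation scenario: planted marker responses around a reservoir
#'
#' Defines the study conditions for the synthetic perturbation experiment:
#' per-marker planted fractional changes at the reservoir, the spatial decay
#' kernel of the effect, baseline marker densities and the number of tumors.
#' The per-marker intensity law is
#' `lambda_m(r) = baseline_m * (1 + effect_m * k(r))` with `k(0) = 1` and
#' `k` clipped to 0 beyond `decay_length`. The default kernel is flat
#' (`k = 1` inside the ROI), so the planted fractional change is directly
#' recoverable as the pooled-ROI fold change.
#'
#' Marker flags are nested (CD8+ and FOXP3+ cells are also CD3+); the
#' generator derives a CD3-only intensity from the three marker laws, which
#' must remain non-negative.
#'
#' @param name Scenario label; used as the condition label in layouts.
#' @param marker_effects Named numeric vector over `CD3`, `CD8`, `FOXP3`
#'   (dimensionless fractional change at the reservoir, each > -1; missing
#'   markers default to 0).
#' @param decay_length Spatial scale of the effect in micrometres.
#' @param baseline_density Named vector of baseline marker densities in
#'   cells/mm^2 (`CD3` must be >= `CD8 + FOXP3`).
#' @param tumor_cell_density Marker-negative (tumor) cell density, cells/mm^2.
#' @param n_tumors Number of simulated tumors (one device each).
#' @param seed Integer seed; the same scenario and seed give bit-identical output.
#' @param kernel `"flat"` or `"exponential"` decay kernel.
#' @return An object of class `perturbation_scenario`.
#' @seealso [perturbation_preset()], [gen_device_tumor()]
#' @export
perturbation_scenario <- function(name = "custom",
                                  marker_effects = c(CD3 = 0, CD8 = 0, FOXP3 = 0),
                                  decay_length = 1200,
                                  baseline_density = c(CD3 = 150, CD8 = 60, FOXP3 = 30),
                                  tumor_cell_density = 2500,
                                  n_tumors = 6,
                                  seed = 1L,
                                  kernel = c("flat", "exponential")) {
  kernel <- match.arg(kernel)
  eff <- c(CD3 = 0, CD8 = 0, FOXP3 = 0)
  if (length(marker_effects)) {
    bad <- setdiff(names(marker_effects), MARKERS)
    if (length(bad)) validation_error("unknown marker(s): ", paste(bad, collapse = ", "))
    eff[names(marker_effects)] <- marker_effects
  }
  if (any(eff <= -1))
    validation_error("planted fractional changes must be > -1 (intensity would be negative)")
  base <- c(CD3 = NA_real_, CD8 = NA_real_, FOXP3 = NA_real_)
  base[names(baseline_density)] <- baseline_density
  if (any(is.na(base)) || any(base <= 0))
    validation_error("baseline_density must give a positive density for CD3, CD8 and FOXP3")
  check_number(decay_length, "decay_length", lower = 0, strict_lower = TRUE)
  check_number(tumor_cell_density, "tumor_cell_density", lower = 0, strict_lower = TRUE)
  check_number(n_tumors, "n_tumors", lower = 1)
  # CD3-only intensity must stay non-negative across the kernel range [0, 1]
  for (k in c(0, 1)) {
    only <- base["CD3"] * (1 + eff["CD3"] * k) -
      base["CD8"] * (1 + eff["CD8"] * k) - base["FOXP3"] * (1 + eff["FOXP3"] * k)
    if (only < 0)
      validation_error("derived CD3-only intensity is negative (k = ", k,
                       "); lower CD8/FOXP3 baselines or effects")
  }
  structure(list(name = name, marker_effects = eff, decay_length = decay_length,
                 baseline_density = base, tumor_cell_density = tumor_cell_density,
                 n_tumors = as.integer(n_tumors), seed = as.integer(seed),
                 kernel = kernel),
            class = "perturbation_scenario")
}

#' Named perturbation presets with the reported planted effects
#'
#' Presets encode the reported per-marker percent changes as fractional
#' effects: local arginine or cysteine release raises CD8 density by 75%,
#' sodium lactate lowers it by 50%, pyruvate raises FOXP3 by 60%, ATP lowers
#' it by 70%, glutamine or itaconate raises CD3 by 75%, the LDH inhibitor
#' GNE-140 lowers all three markers by 75%, and the glutathione-synthesis
#' inhibitor BSO lowers CD3 by 50% and CD8 by 75%. `"NULL"` plants no effect.
#'
#' @param name One of `"NULL"`, `"ARG_CD8"`, `"CYS_CD8"`, `"LAC_CD8"`,
#'   `"PYR_FOXP3"`, `"ATP_FOXP3"`, `"GLN_CD3"`, `"ITA_CD3"`, `"GNE140_ALL"`,
#'   `"BSO"`.
#' @param ... Overrides passed to [perturbation_scenario()] (e.g. `seed`,
#'   `n_tumors`).
#' @return A `perturbation_scenario`.
#' @export
perturbation_preset <- function(name, ...) {
  effects <- list(
    "NULL"     = c(CD3 = 0, CD8 = 0, FOXP3 = 0),
    ARG_CD8    = c(CD8 = 0.75),
    CYS_CD8    = c(CD8 = 0.75),
    LAC_CD8    = c(CD8 = -0.50),
    PYR_FOXP3  = c(FOXP3 = 0.60),
    ATP_FOXP3  = c(FOXP3 = -0.70),
    GLN_CD3    = c(CD3 = 0.75),
    ITA_CD3    = c(CD3 = 0.75),
    GNE140_ALL = c(CD3 = -0.75, CD8 = -0.75, FOXP3 = -0.75),
    BSO        = c(CD3 = -0.50, CD8 = -0.75)
  )
  if (!name %in% names(effects))
    validation_error("unknown perturbation preset: ", name)
  args <- list(name = name, marker_effects = effects[[name]])
  args <- utils::modifyList(args, list(...))
  do.call(perturbation_scenario, args)
}

#' Default metabolite universe of the synthetic ion images
#'
#' Forty metabolites spanning the amino-acid, redox, TCA, nucleotide and
#' lipid species quantified in the study, used as channel names for
#' synthetic ion images; scenario effects may add further names.
#' @return Character vector of metabolite names.
#' @export
default_metabolites <- function() {
  c("glutathione", "N-acetyl-cysteine", "cysteine", "cystathionine",
    "methionine", "taurine", "citrate", "succinate", "fumarate", "malate",
    "pyruvate", "lactate", "glucose", "glucose 1-phosphate", "d-Gluconate",
    "galacturonic acid", "mucic acid", "glutamine", "glutamate", "arginine",
    "histidine", "alanine", "serine", "aspartate", "creatine", "carnitine",
    "kynurenic acid", "itaconate", "ATP", "ADP", "AMP", "dCMP", "orotate",
    "hypoxanthine", "inosine", "uracil", "NAD", "myristic acid",
    "oleic acid", "palmitic acid")
}

#' Metabolomics scenario: hotspots with planted metabolite enrichment
#'
#' Defines a synthetic dual-modality section: marker-positive cells
#' clustered at hotspot centres over a sparse background, plus a
#' co-registered multi-channel ion image whose per-pixel counts are
#' negative-binomial with log2 mean
#' `baseline + effect * hotspot_membership + smooth field`, the field being
#' shared across channels (section-thickness / matrix effects).
#'
#' @param name Scenario label.
#' @param hotspot_marker Marker whose cells form the hotspots.
#' @param metabolite_effects Named numeric vector: planted log2 change of
#'   each metabolite inside hotspots. Names not in `metabolites` are added.
#' @param n_hotspots Number of hotspots (>= 1).
#' @param pixel_size Ion-image raster width in micrometres.
#' @param grid_extent Grid extent `c(width, height)` in micrometres.
#' @param count_noise Overdispersion `phi` of the count model
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param seed Integer seed.
#' @param hotspot_radius Hotspot disc radius in micrometres.
#' @param cells_per_hotspot Expected marker-positive cells per hotspot.
#' @param background_cell_density Background marker-positive density, cells/mm^2.
#' @param field_sd Standard deviation (log2) of the smooth spatial field.
#' @param metabolites Channel names (default [default_metabolites()]).
#' @return An object of class `metabolomics_scenario`.
#' @seealso [metabolomics_preset()], [gen_ion_image()]
#' @export
metabolomics_scenario <- function(name = "custom",
                                  hotspot_marker = "CD8",
                                  metabolite_effects = numeric(0),
                                  n_hotspots = 6,
                                  pixel_size = 125,
                                  grid_extent = c(10000, 10000),
                                  count_noise = 0.05,
                                  seed = 1L,
                                  hotspot_radius = 400,
                                  cells_per_hotspot = 80,
                                  background_cell_density = 3,
                                  field_sd = 0.2,
                                  metabolites = default_metabolites()) {
  if (!hotspot_marker %in% MARKERS)
    validation_error("hotspot_marker must be one of ", paste(MARKERS, collapse = ", "))
  check_number(n_hotspots, "n_hotspots", lower = 1)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(count_noise, "count_noise", lower = 0)
  check_number(hotspot_radius, "hotspot_radius", lower = 0, strict_lower = TRUE)
  if (length(grid_extent) != 2L || any(!is.finite(grid_extent)) || any(grid_extent <= 0))
    validation_error("grid_extent must be two positive extents in micrometres")
  mets <- union(metabolites, names(metabolite_effects))
  if (anyDuplicated(mets)) validation_error("metabolite names must be unique")
  eff <- stats::setNames(numeric(length(mets)), mets)
  eff[names(metabolite_effects)] <- metabolite_effects
  structure(list(name = name, hotspot_marker = hotspot_marker,
                 metabolite_effects = eff, n_hotspots = as.integer(n_hotspots),
                 pixel_size = pixel_size, grid_extent = grid_extent,
                 count_noise = count_noise, seed = as.integer(seed),
                 hotspot_radius = hotspot_radius,
                 cells_per_hotspot = cells_per_hotspot,
                 background_cell_density = background_cell_density,
                 field_sd = field_sd, metabolites = mets),
            class = "metabolomics_scenario")
}

#' Named metabolomics presets with the reported enrichment directions
#'
#' `"CD8_HOTSPOT"` plants glutathione and N-acetyl-cysteine up (+1 log2) in
#' CD8-high regions; `"FOXP3_HOTSPOT"` plants citrate up and the lipids
#' myristic acid and oleic acid down in FOXP3-high regions; `"NULL"` plants
#' nothing. `"OPPOSITE7"` returns a *pair* of scenarios (CD8 and FOXP3) in
#' which exactly seven metabolites - cystathionine, d-Gluconate, dCMP,
#' galacturonic acid, glucose 1-phosphate, mucic acid and orotate - carry
#' antagonistic signs between the two hotspot types while two further
#' metabolites are planted concordantly (same sign in both).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [metabolomics_scenario()].
#' @return A `metabolomics_scenario`, or for `"OPPOSITE7"` a named list of
#'   two (`cd8`, `foxp3`).
#' @export
metabolomics_preset <- function(name, ...) {
  dots <- list(...)
  mk <- function(args) do.call(metabolomics_scenario, utils::modifyList(args, dots))
  switch(name,
    "NULL" = mk(list(name = "NULL", hotspot_marker = "CD8")),
    CD8_HOTSPOT = mk(list(
      name = "CD8_HOTSPOT", hotspot_marker = "CD8",
      metabolite_effects = c("glutathione" = 1, "N-acetyl-cysteine" = 1))),
    FOXP3_HOTSPOT = mk(list(
      name = "FOXP3_HOTSPOT", hotspot_marker = "FOXP3",
      metabolite_effects = c("citrate" = 1, "myristic acid" = -1, "oleic acid" = -1))),
    OPPOSITE7 = {
      seven <- c("cystathionine", "d-Gluconate", "dCMP", "galacturonic acid",
                 "glucose 1-phosphate", "mucic acid", "orotate")
      concordant <- c("taurine" = 0.8, "succinate" = -0.8)
      seed <- if (!is.null(dots$seed)) as.integer(dots$seed) else 1L
      dots$seed <- NULL
      mk2 <- function(args) do.call(metabolomics_scenario, utils::modifyList(args, dots))
      list(
        cd8 = mk2(list(name = "OPPOSITE7_CD8", hotspot_marker = "CD8", seed = seed,
                       metabolite_effects = c(stats::setNames(rep(1, 7), seven), concordant))),
        foxp3 = mk2(list(name = "OPPOSITE7_FOXP3", hotspot_marker = "FOXP3", seed = seed + 1L,
                         metabolite_effects = c(stats::setNames(rep(-1, 7), seven), concordant))))
    },
    validation_error("unknown metabolomics preset: ", name)
  )
}

#' Default gene universe and gene sets for synthetic ST ROIs
#'
#' A compact universe: curated metabolic gene sets (amino-acid metabolism,
#' TCA cycle / respiration, glycolysis), a housekeeping set usable as the
#' normalization target group, and unannotated filler genes.
#' @return Named list with `genes` (character) and `gene_sets` (named list).
#' @export
default_gene_universe <- function() {
  gene_sets <- list(
    amino_acid_metabolism = c("GLS", "GLUL", "GOT1", "GOT2", "ASNS", "BCAT1",
                              "BCAT2", "CTH", "CBS", "ASS1", "ARG2", "ODC1",
                              "PSAT1", "PHGDH", "SHMT2"),
    tca_respiration = c("CS", "IDH2", "IDH3A", "SDHA", "SDHB", "FH", "MDH2",
                        "OGDH", "SUCLA2", "ACO2"),
    glycolysis = c("HK2", "GPI", "PFKM", "ALDOA", "GAPDH", "PGK1", "ENO1",
                   "PKM", "LDHA", "SLC2A1"),
    housekeeping = c("ACTB", "B2M", "GUSB", "HPRT1", "POLR2A", "PPIA",
                     "RPL19", "TBP", "TUBB", "UBC")
  )
  filler <- sprintf("GENE%03d", seq_len(150))
  list(genes = c(unique(unlist(gene_sets)), filler), gene_sets = gene_sets)
}

#' Spatial-transcriptomics scenario: CD8-classified ROIs with planted shifts
#'
#' Generates ROIs whose CD8 positive indices fall inside the class bands
#' implied by `class_counts` (high > 20%, intermediate (5%, 20%], low < 5%)
#' and whole-transcriptome expression vectors with planted log2 shifts of
#' whole gene sets in CD8-high ROIs.
#'
#' @param class_counts Named or positional counts `c(high, intermediate, low)`.
#' @param genes Gene names (unique, non-empty).
#' @param gene_sets Named list of gene sets (subsets of `genes`).
#' @param pathway_effects Named numeric vector: planted log2 change, in
#'   CD8-high ROIs, of every gene in the named set of `gene_sets`.
#' @param seed Integer seed.
#' @param nuclei_mean Mean nuclei count per ROI.
#' @param noise_sd Per-gene expression noise sd on the log2 scale.
#' @return An object of class `st_scenario`.
#' @seealso [gen_st_rois()], [st_preset()]
#' @export
st_scenario <- function(class_counts = c(high = 9, intermediate = 12, low = 9),
                        genes = default_gene_universe()$genes,
                        gene_sets = default_gene_universe()$gene_sets,
                        pathway_effects = numeric(0),
                        seed = 1L,
                        nuclei_mean = 2000,
                        noise_sd = 0.25) {
  if (length(class_counts) != 3L || any(class_counts < 0))
    validation_error("class_counts must be three non-negative counts (high, intermediate, low)")
  if (is.null(names(class_counts))) names(class_counts) <- c("high", "intermediate", "low")
  if (length(genes) == 0L) validation_error("gene list must be non-empty")
  if (anyDuplicated(genes)) validation_error("gene names must be unique")
  if (length(pathway_effects)) {
    bad <- setdiff(names(pathway_effects), names(gene_sets))
    if (length(bad)) validation_error("pathway_effects name(s) not in gene_sets: ",
                                      paste(bad, collapse = ", "))
  }
  structure(list(class_counts = class_counts, genes = genes, gene_sets = gene_sets,
                 pathway_effects = pathway_effects, seed = as.integer(seed),
                 nuclei_mean = nuclei_mean, noise_sd = noise_sd),
            class = "st_scenario")
}

#' ST preset with the reported class composition and amino-acid enrichment
#'
#' `"AA_HIGH"` uses the reported 9/12/9 high/intermediate/low composition of
#' 30 ROIs and plants a +1 log2 shift of the amino-acid-metabolism gene set
#' in CD8-high ROIs; `"NULL"` keeps the composition with no planted shift.
#'
#' @param name `"AA_HIGH"` or `"NULL"`.
#' @param ... Overrides passed to [st_scenario()].
#' @return An `st_scenario`.
#' @export
st_preset <- function(name, ...) {
  switch(name,
    AA_HIGH = do.call(st_scenario, utils::modifyList(
      list(pathway_effects = c(amino_acid_metabolism = 1)), list(...))),
    "NULL" = do.call(st_scenario, list(...)),
    validation_error("unknown ST preset: ", name))
}
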