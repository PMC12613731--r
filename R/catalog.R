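# Fixed 72-region catalog: 34 Desikan-Killiany cortical parcels per hemisphere
# (thickness, mm) plus bilateral hippocampus and amygdala (volume, mm^3).

.dk_parcels <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

.lobe_map <- c(
  bankssts = "temporal", caudalanteriorcingulate = "cingulate",
  caudalmiddlefrontal = "frontal", cuneus = "occipital",
  entorhinal = "temporal", frontalpole = "frontal", fusiform = "temporal",
  inferiorparietal = "parietal", inferiortemporal = "temporal",
  insula = "insula", isthmuscingulate = "cingulate",
  lateraloccipital = "occipital", lateralorbitofrontal = "frontal",
  lingual = "occipital", medialorbitofrontal = "frontal",
  middletemporal = "temporal", paracentral = "frontal",
  parahippocampal = "temporal", parsopercularis = "frontal",
  parsorbitalis = "frontal", parstriangularis = "frontal",
  pericalcarine = "occipital", postcentral = "parietal",
  posteriorcingulate = "cingulate", precentral = "frontal",
  precuneus = "parietal", rostralanteriorcingulate = "cingulate",
  rostralmiddlefrontal = "frontal", superiorfrontal = "frontal",
  superiorparietal = "parietal", superiortemporal = "temporal",
  supramarginal = "parietal", temporalpole = "temporal",
  transversetemporal = "temporal")

.aseg_names <- c(
  lh_hippocampus = "Left-Hippocampus", rh_hippocampus = "Right-Hippocampus",
  lh_amygdala = "Left-Amygdala", rh_amygdala = "Right-Amygdala")

#' The fixed 72-region catalog
#'
#' 68 cortical thickness regions (34 Desikan-Killiany parcels in each
#' hemisphere) plus left/right hippocampus and amygdala volumes. Region ids
#' use `<hemi>_<parcel>` naming (`lh_entorhinal`, `rh_hippocampus`, ...);
#' the `fs_name` column carries the name used in FreeSurfer stats tables.
#'
#' @return A tibble with columns `region`, `hemi`, `parcel`, `metric`
#'   (`"thickness"` or `"volume"`), `lobe` and `fs_name`, with exactly 72 rows.
#' @export
region_catalog <- function() {
  cortical <- tibble::tibble(
    hemi = rep(c("lh", "rh"), each = length(.dk_parcels)),
    parcel = rep(.dk_parcels, 2L))
  cortical <- dplyr::mutate(cortical,
    region = paste(.data$hemi, .data$parcel, sep = "_"),
    metric = "thickness",
    lobe = unname(.lobe_map[.data$parcel]),
    fs_name = .data$parcel)
  subcort <- tibble::tibble(
    hemi = rep(c("lh", "rh"), 2L),
    parcel = rep(c("hippocampus", "amygdala"), each = 2L),
    region = c("lh_hippocampus", "rh_hippocampus",
               "lh_amygdala", "rh_amygdala"),
    metric = "volume",
    lobe = "subcortical",
    fs_name = unname(.aseg_names[c("lh_hippocampus", "rh_hippocampus",
                                   "lh_amygdala", "rh_amygdala")]))
  dplyr::select(dplyr::bind_rows(cortical, subcort),
                "region", "hemi", "parcel", "metric", "lobe", "fs_name")
}

#' A-priori regions of interest for Alzheimer-type atrophy
#'
#' The signature set used for combined discrimination models: amygdala and
#' hippocampal volume plus entorhinal, inferior temporal, middle temporal,
#' precuneus and inferior parietal thickness. Left and right structures are
#' listed separately (14 regions).
#'
#' @return Character vector of region ids.
#' @export
ad_signature_regions <- function() {
  parcels <- c("hippocampus", "amygdala", "entorhinal", "inferiortemporal",
               "middletemporal", "precuneus", "inferiorparietal")
  as.vector(outer(c("lh", "rh"), parcels, paste, sep = "_"))
}

#' Regions analysed against regional tau uptake
#'
#' All cortical regions plus amygdala; the hippocampus is excluded because
#' hippocampal tau PET signal is contaminated by off-target tracer binding
#' in the choroid plexus (70 regions).
#'
#' @return Character vector of 70 region ids.
#' @export
tau_regions <- function() {
  cat <- region_catalog()
  setdiff(cat$region, c("lh_hippocampus", "rh_hippocampus"))
}

temporal_regions <- function() {
  cat <- region_catalog()
  cat$region[cat$lobe == "temporal"]
}
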