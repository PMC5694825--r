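#' Region labels for the 90-region cortical/subcortical parcellation
#'
#' Returns an ordered character vector of anatomical region labels in the
#' conventional left/right interleaved order of the 90-region automated
#' anatomical labelling scheme. For other sizes, generic `R<i>_L/R` labels
#' are produced so any square matrix can be analysed.
#'
#' @param n_regions Number of regions (default 90).
#' @return Character vector of length `n_regions`.
#' @export
#' @examples
#' head(region_labels(90))
region_labels <- function(n_regions = 90) {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  if (n_regions == 2L * length(base)) {
    as.vector(t(outer(base, c("_L", "_R"), paste0)))
  } else {
    hemi <- rep(c("_L", "_R"), length.out = n_regions)
    paste0("R", sprintf("%02d", ceiling(seq_len(n_regions) / 2)), hemi)
  }
}

#' Named brain-region feature sets used by the prediction models
#'
#' The three a-priori regions entering Model 2 (right middle orbitofrontal,
#' right inferior parietal, right mesial superior frontal), and the default
#' five regions carrying the planted clustering deficit in synthetic cohorts
#' (left lingual, left calcarine, right insula, right middle temporal, right
#' olfactory).
#'
#' @return Character vector of region labels.
#' @export
model2_regions <- function() {
  c("Frontal_Mid_Orb_R", "Parietal_Inf_R", "Frontal_Sup_Medial_R")
}

#' @rdname model2_regions
#' @export
default_predictive_regions <- function() {
  c("Lingual_L", "Calcarine_L", "Insula_R", "Temporal_Mid_R", "Olfactory_R")
}
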