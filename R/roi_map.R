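# Atlas-region to ROI mapping.

aal82_names <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Heschl",
    "Temporal_Sup", "Temporal_Pole_Sup", "Temporal_Mid",
    "Temporal_Pole_Mid", "Temporal_Inf"
  )
  c(paste0(base, "_L"), paste0(base, "_R"))
}

aal82_lobe <- function(region) {
  stem <- sub("_(L|R)$", "", region)
  side <- sub("^.*_(L|R)$", "\\1", region)
  lobe <- c(
    Precentral = "Frontal", Frontal_Sup = "Frontal", Frontal_Sup_Orb = "Frontal",
    Frontal_Mid = "Frontal", Frontal_Mid_Orb = "Frontal",
    Frontal_Inf_Oper = "Frontal", Frontal_Inf_Tri = "Frontal",
    Frontal_Inf_Orb = "Frontal", Supp_Motor_Area = "Frontal",
    Olfactory = "Frontal", Frontal_Sup_Medial = "Frontal",
    Frontal_Med_Orb = "Frontal", Rectus = "Frontal",
    Rolandic_Oper = "Temporal", Insula = "Temporal", Hippocampus = "Temporal",
    ParaHippocampal = "Temporal", Amygdala = "Temporal", Fusiform = "Temporal",
    Heschl = "Temporal", Temporal_Sup = "Temporal",
    Temporal_Pole_Sup = "Temporal", Temporal_Mid = "Temporal",
    Temporal_Pole_Mid = "Temporal", Temporal_Inf = "Temporal",
    Postcentral = "Parietal", Parietal_Sup = "Parietal",
    Parietal_Inf = "Parietal", SupraMarginal = "Parietal",
    Angular = "Parietal", Precuneus = "Parietal",
    Paracentral_Lobule = "Parietal",
    Calcarine = "Occipital", Cuneus = "Occipital", Lingual = "Occipital",
    Occipital_Sup = "Occipital", Occipital_Mid = "Occipital",
    Occipital_Inf = "Occipital",
    Cingulum_Ant = "Cingulate", Cingulum_Mid = "Cingulate",
    Cingulum_Post = "Cingulate"
  )
  paste0(lobe[stem], "_", side)
}

#' Default atlas-region to ROI map
#'
#' The 82 cortical/limbic atlas regions (41 per hemisphere; subcortical
#' nuclei excluded) merged into 10 cohesive ROIs: lateralised frontal,
#' temporal (including the hippocampal formation, insula and Rolandic
#' operculum), parietal, occipital and cingulate groups. Regions belonging
#' to the same cortical gyrus, or neighbouring regions with established
#' functional coupling, share a ROI.
#'
#' @return A data frame with columns `region` and `roi`.
#' @export
default_roi_map <- function() {
  region <- aal82_names()
  load_roi_map(data.frame(region = region, roi = aal82_lobe(region),
                          stringsAsFactors = FALSE))
}

#' Load and validate an atlas-region to ROI map
#'
#' @param x A two-column data frame (`region`, `roi`) or the path of a
#'   two-column TSV/CSV file.
#' @param strict If `TRUE` (default) the map must cover exactly 82 regions
#'   merged into 10 ROIs; set `FALSE` for toy maps.
#' @return A validated `roi_map` data frame.
#' @export
load_roi_map <- function(x, strict = TRUE) {
  if (is.character(x) && length(x) == 1) {
    sep <- if (grepl("\\.csv$", x)) "," else "\t"
    x <- utils::read.table(x, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || !all(c("region", "roi") %in% names(x))) {
    stop("roi map needs columns 'region' and 'roi'")
  }
  x <- x[, c("region", "roi")]
  if (anyDuplicated(x$region)) {
    stop("validation error: region mapped twice: ",
         paste(unique(x$region[duplicated(x$region)]), collapse = ", "))
  }
  if (strict) {
    if (nrow(x) != 82) {
      stop("validation error: strict map must cover 82 regions, got ", nrow(x))
    }
    if (length(unique(x$roi)) != 10) {
      stop("validation error: strict map must define 10 ROIs, got ",
           length(unique(x$roi)))
    }
  }
  class(x) <- c("roi_map", "data.frame")
  x
}
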