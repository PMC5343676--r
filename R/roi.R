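#' Desikan-style cortical parcellation labels
#'
#' The 34 cortical regions of interest defined per hemisphere in the
#' Desikan-Killiany atlas, optionally prefixed by hemisphere
#' (`lh_`/`rh_`, 68 labels total).
#'
#' @param hemispheres If `TRUE` (default) return the 68 hemisphere-prefixed
#'   labels; otherwise the 34 base region names.
#' @return Character vector of ROI labels.
#' @examples
#' length(desikan_rois())            # 68
#' head(desikan_rois(hemispheres = FALSE))
#' @export
desikan_rois <- function(hemispheres = TRUE) {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
    "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
    "insula")
  if (!hemispheres) return(base)
  c(paste0("lh_", base), paste0("rh_", base))
}
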