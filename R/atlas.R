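#' White matter tract atlas (JHU ICBM-DTI-81)
#'
#' The 48 labelled white matter tracts of the JHU ICBM-DTI-81 atlas, in the
#' standard label order, together with their laterality and the column slugs
#' used for FA/MD columns in tract tables (`fa_<slug>`, `md_<slug>`).
#'
#' @return A data.frame with columns `tract` (label), `laterality`
#'   (`"left"`, `"right"` or `"commissural"`) and `slug`.
#' @examples
#' atlas <- jhu_atlas()
#' nrow(atlas)  # 48
#' @export
jhu_atlas <- function() {
  midline <- c(
    "Middle cerebellar peduncle",
    "Pontine crossing tract",
    "Genu of corpus callosum",
    "Body of corpus callosum",
    "Splenium of corpus callosum",
    "Fornix (column and body)"
  )
  paired <- c(
    "Corticospinal tract",
    "Medial lemniscus",
    "Inferior cerebellar peduncle",
    "Superior cerebellar peduncle",
    "Cerebral peduncle",
    "Anterior limb of internal capsule",
    "Posterior limb of internal capsule",
    "Retrolenticular part of internal capsule",
    "Anterior corona radiata",
    "Superior corona radiata",
    "Posterior corona radiata",
    "Posterior thalamic radiation",
    "Sagittal stratum",
    "External capsule",
    "Cingulum (cingulate gyrus)",
    "Cingulum (hippocampus)",
    "Fornix (cres) / Stria terminalis",
    "Superior longitudinal fasciculus",
    "Superior fronto-occipital fasciculus",
    "Uncinate fasciculus",
    "Tapetum"
  )
  # JHU ICBM-DTI-81 orders each bilateral structure right then left
  tract <- c(midline, as.vector(rbind(paste(paired, "R"), paste(paired, "L"))))
  laterality <- c(
    rep("commissural", length(midline)),
    rep(c("right", "left"), length(paired))
  )
  stopifnot(length(tract) == 48L, !anyDuplicated(tract))
  data.frame(
    tract = tract,
    laterality = laterality,
    slug = tract_slug(tract),
    stringsAsFactors = FALSE
  )
}

#' Turn tract labels into column slugs
#'
#' @param x character vector of tract labels.
#' @return lower-case slugs with non-alphanumerics collapsed to `_`.
#' @keywords internal
tract_slug <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_+|_+$", "", s)
}

#' Names of the FA and MD columns of a tract table
#'
#' @param atlas atlas data.frame from [jhu_atlas()].
#' @return list with components `fa` and `md`, each of 48 column names.
#' @export
tract_columns <- function(atlas = jhu_atlas()) {
  list(fa = paste0("fa_", atlas$slug), md = paste0("md_", atlas$slug))
}
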