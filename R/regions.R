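#' Atlas region labels for one hemisphere
#'
#' Returns the fixed list of 56 gray-matter region labels (one hemisphere,
#' Neuromorphometrics-style naming, ventricular/brainstem/white-matter/CSF
#' structures excluded) used throughout the package. The anterior and
#' posterior insula appear as separate regions because nodal metrics are
#' reported there.
#'
#' @return Character vector of length 56, unique labels.
#' @export
atlas_regions <- function() {
  c(
    # subcortical gray
    "accumbens area", "amygdala", "caudate", "hippocampus", "pallidum",
    "putamen", "thalamus", "basal forebrain",
    # insular / opercular
    "anterior insula", "posterior insula", "central operculum",
    "frontal operculum", "parietal operculum",
    # frontal
    "anterior cingulate gyrus", "anterior orbital gyrus", "frontal pole",
    "gyrus rectus", "lateral orbital gyrus", "medial frontal cortex",
    "medial orbital gyrus", "middle cingulate gyrus", "middle frontal gyrus",
    "opercular inferior frontal gyrus", "orbital inferior frontal gyrus",
    "posterior orbital gyrus", "precentral gyrus",
    "precentral gyrus medial segment", "subcallosal area",
    "superior frontal gyrus", "superior frontal gyrus medial segment",
    "supplementary motor cortex", "triangular inferior frontal gyrus",
    # temporal
    "entorhinal area", "fusiform gyrus", "inferior temporal gyrus",
    "middle temporal gyrus", "parahippocampal gyrus", "planum polare",
    "planum temporale", "superior temporal gyrus", "temporal pole",
    "transverse temporal gyrus",
    # parietal
    "angular gyrus", "postcentral gyrus",
    "postcentral gyrus medial segment", "posterior cingulate gyrus",
    "precuneus", "superior parietal lobule", "supramarginal gyrus",
    # occipital
    "calcarine cortex", "cuneus", "inferior occipital gyrus",
    "lingual gyrus", "middle occipital gyrus", "occipital fusiform gyrus",
    "superior occipital gyrus"
  )
}

#' Locate the insular nodes in a label set
#'
#' Resolves the anterior and posterior insula to node indices by exact label
#' match. Each must resolve to exactly one node, otherwise the run aborts:
#' downstream nodal metrics are reported at these two nodes only.
#'
#' @param labels Character vector of region labels.
#' @return Named integer vector `c(aIns = ..., pIns = ...)`.
#' @export
insula_nodes <- function(labels = atlas_regions()) {
  a <- which(labels == "anterior insula")
  p <- which(labels == "posterior insula")
  if (length(a) != 1L || length(p) != 1L) {
    stop("labels must contain exactly one 'anterior insula' and one ",
         "'posterior insula' entry (found ", length(a), " and ", length(p), ")")
  }
  c(aIns = a, pIns = p)
}

# Lobe-like grouping used by the default block correlation structure.
region_lobe_blocks <- function() {
  labs <- atlas_regions()
  blocks <- list(
    subcortical = labs[1:8],
    insular_opercular = labs[9:13],
    frontal = labs[14:32],
    temporal = labs[33:42],
    parietal = labs[43:49],
    occipital = labs[50:56]
  )
  lapply(blocks, function(b) match(b, labs))
}
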