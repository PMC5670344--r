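#' Default white-matter ROI vocabulary
#'
#' The tract regions of interest used for fractional-anisotropy (FA)
#' screening: 28 (tract, side) rows covering the major white-matter bundles
#' reported vulnerable to mild traumatic brain injury (corpus callosum,
#' cingulum, corticopontine and corticospinal tracts, fornix, cerebellar
#' peduncles, the longitudinal and fronto-occipital fasciculi, optic
#' radiation, uncinate fasciculus). Each row carries a baseline FA typical of
#' healthy adults, used by the synthetic cohort generator as the ROI's mean.
#'
#' @return data.frame with columns `roi`, `side`, `baseline_fa`.
#' @export
default_roi_vocabulary <- function() {
  rows <- list(
    c("corpus_callosum", "front",     0.361),
    c("corpus_callosum", "posterior", 0.415),
    c("corpus_callosum", "superior",  0.412),
    c("cingulum", "left",  0.337),
    c("cingulum", "right", 0.345),
    c("corticopontine_tract", "left",  0.412),
    c("corticopontine_tract", "right", 0.417),
    c("corticospinal_tract", "left",  0.422),
    c("corticospinal_tract", "right", 0.408),
    c("fornix", "left",  0.296),
    c("fornix", "right", 0.300),
    c("inferior_cerebellar_peduncle", "left",  0.289),
    c("inferior_cerebellar_peduncle", "right", 0.285),
    c("inferior_fronto_occipital_fasciculus", "left",  0.339),
    c("inferior_fronto_occipital_fasciculus", "right", 0.341),
    c("inferior_longitudinal_fasciculus", "left",  0.358),
    c("inferior_longitudinal_fasciculus", "right", 0.349),
    c("middle_cerebellar_peduncle", "none", 0.332),
    c("optic_radiation", "left",  0.392),
    c("optic_radiation", "right", 0.377),
    c("superior_cerebellar_peduncle", "left",  0.331),
    c("superior_cerebellar_peduncle", "right", 0.303),
    c("superior_fronto_occipital_fasciculus", "left",  0.351),
    c("superior_fronto_occipital_fasciculus", "right", 0.343),
    c("superior_longitudinal_fasciculus", "left",  0.368),
    c("superior_longitudinal_fasciculus", "right", 0.355),
    c("uncinate_fasciculus", "left",  0.281),
    c("uncinate_fasciculus", "right", 0.301)
  )
  data.frame(
    roi = vapply(rows, `[`, "", 1L),
    side = vapply(rows, `[`, "", 2L),
    baseline_fa = as.numeric(vapply(rows, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}
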