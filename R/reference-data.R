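#' Published composition of the reference liver ultrasound collection
#'
#' Per-type image and case counts of the multi-center Japanese liver tumor
#' ultrasound collection (JSUM, supported by AMED; 11 hospitals, still
#' B-mode images) that the synthetic phantom generator is proportioned to,
#' together with the published per-split training/test image counts of its
#' three case-disjoint 8:2 divisions. The images themselves are
#' ethics-restricted and are not part of this package; only these published
#' counts are shipped, as plain CSV under `inst/extdata`.
#'
#' @return A list of two `data.frame`s: `composition` (columns `tumor_type`,
#'   `images`, `cases`) and `splits` (columns `split`, `tumor_type`,
#'   `training`, `test`).
#' @export
#' @examples
#' ref <- liver_reference_counts()
#' sum(ref$composition$images)   # 7607 images over 1996 cases
liver_reference_counts <- function() {
  dir <- system.file("extdata", package = "dlratio")
  list(composition = read.csv(file.path(dir, "liver_collection_composition.csv"),
                              stringsAsFactors = FALSE),
       splits = read.csv(file.path(dir, "liver_collection_splits.csv"),
                         stringsAsFactors = FALSE))
}
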