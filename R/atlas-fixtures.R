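#' Packaged atlas fixtures: extended and restricted structure sets
#'
#' The package ships two small CSV fixtures describing the node sets of the
#' two connectome variants: an extended 104-structure set that includes the
#' brainstem and other deep structures, and the 20-structure removal list
#' whose application leaves the 84-structure restricted set of a
#' Desikan-Killiany-style atlas (68 cortical regions, 14 subcortical
#' structures, 2 cerebellar cortices). Structure names follow the FreeSurfer
#' aseg/aparc convention; the volumes are synthetic plausible values (the
#' fixture filenames carry a `_synthetic` suffix for this reason), intended
#' for exercising the volume-normalization logic, not as measured anatomy.
#'
#' @return `extended_atlas()`: a [parcellation] of 104 structures with the
#'   brainstem flagged as hub and communities 1/2/3 = left/right/midline.
#'   `removed_structures()`: character vector of the 20 removed names.
#'   `restricted_atlas()`: the 84-structure [parcellation] left after
#'   removal.
#' @export
extended_atlas <- function() {
  path <- system.file("extdata", "atlas_extended_synthetic.csv",
                      package = "brainhub", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_hub <- df$name == "Brain-Stem"
  df$community <- ifelse(grepl("^(Left-|ctx-lh-)", df$name), 1L,
                         ifelse(grepl("^(Right-|ctx-rh-)", df$name), 2L, 3L))
  parcellation(df)
}

#' @rdname extended_atlas
#' @export
removed_structures <- function() {
  path <- system.file("extdata", "atlas_removed_synthetic.csv",
                      package = "brainhub", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)$name
}

#' @rdname extended_atlas
#' @export
restricted_atlas <- function() {
  ext <- extended_atlas()
  keep <- !(ext$name %in% removed_structures())
  parcellation(as.data.frame(ext)[keep, , drop = FALSE])
}
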