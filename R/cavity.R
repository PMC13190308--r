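# Anatomical site vocabulary and cavity classification.
#
# Metastatic sites are classified as intrathoracic (within the chest cavity)
# or extrathoracic. Chest wall and diaphragm lesions are ambiguous: their
# cavity depends on whether the lesion arose inside or outside the pleural
# boundary, so they require an explicit qualifier.

# canonical controlled vocabulary (19 sites)
.cs_sites <- c(
  "lung"                      = "intrathoracic",
  "mediastinal lymph node"    = "intrathoracic",
  "mediastinal soft tissue"   = "intrathoracic",
  "pleura"                    = "intrathoracic",
  "chest wall"                = "qualifier",
  "diaphragm"                 = "qualifier",
  "axillary lymph node"       = "extrathoracic",
  "cervical lymph node"       = "extrathoracic",
  "supraclavicular lymph node" = "extrathoracic",
  "abdominopelvic lymph node" = "extrathoracic",
  "soft tissue"               = "extrathoracic",
  "cardiac"                   = "extrathoracic",
  "bone"                      = "extrathoracic",
  "liver"                     = "extrathoracic",
  "brain"                     = "extrathoracic",
  "gastric"                   = "extrathoracic",
  "adrenal gland"             = "extrathoracic",
  "kidney"                    = "extrathoracic",
  "peritoneum"                = "extrathoracic"
)

#' Anatomical site vocabulary
#'
#' @return data frame of canonical site names and their default cavity class
#'   (`"qualifier"` marks sites whose cavity depends on the pleural-boundary
#'   qualifier).
#' @export
site_vocabulary <- function() {
  data.frame(anatomical_site = names(.cs_sites),
             cavity = unname(.cs_sites),
             stringsAsFactors = FALSE)
}

# alias resolution, shipped as extdata so users can inspect/extend it
site_aliases <- function() {
  path <- system.file("extdata", "site_aliases.tsv", package = "cloneseed")
  if (nzchar(path) && file.exists(path)) {
    al <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    stats::setNames(al$canonical, al$alias)
  } else {
    character(0)
  }
}

#' Classify an anatomical site as intrathoracic or extrathoracic
#'
#' Mediastinal nodes/soft tissue, lung and pleura are intrathoracic; distant
#' nodal basins, viscera, bone and brain are extrathoracic. Chest wall and
#' diaphragm lesions take their cavity from the pleural-boundary qualifier
#' and error without one. The primary tumour is its own cavity class.
#'
#' @param anatomical_site site name (canonical or a shipped alias).
#' @param qualifier `"inside_pleura"` or `"outside_pleura"`; required for
#'   chest wall and diaphragm, ignored otherwise.
#' @param tumour_kind `"metastasis"` or `"primary"`.
#' @return one of `"intrathoracic"`, `"extrathoracic"`, `"primary"`.
#' @examples
#' classify_cavity("liver")
#' classify_cavity("mediastinal lymph node")
#' classify_cavity("chest wall", qualifier = "outside_pleura")
#' @export
classify_cavity <- function(anatomical_site, qualifier = NULL,
                            tumour_kind = "metastasis") {
  if (identical(tumour_kind, "primary")) return("primary")
  site <- tolower(trimws(anatomical_site))
  al <- site_aliases()
  if (site %in% names(al)) site <- unname(al[[site]])
  if (!site %in% names(.cs_sites)) {
    stop("unknown anatomical site: '", anatomical_site,
         "' (not in the controlled vocabulary)", call. = FALSE)
  }
  cls <- unname(.cs_sites[[site]])
  if (cls != "qualifier") return(cls)
  if (is.null(qualifier) || is.na(qualifier) || !nzchar(qualifier)) {
    stop("site '", site, "' requires a pleural-boundary qualifier ",
         "(inside_pleura/outside_pleura)", call. = FALSE)
  }
  switch(match.arg(qualifier, c("inside_pleura", "outside_pleura")),
         inside_pleura = "intrathoracic",
         outside_pleura = "extrathoracic")
}
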