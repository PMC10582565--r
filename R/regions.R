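#' Controlled brain-region vocabulary
#'
#' The default registry holds the 20 region abbreviations used for the
#' whole-brain connectivity network (supramarginal gyrus through cerebellum).
#' Registries are ordinary data frames with columns `code` and `name`;
#' lookups are case-insensitive and unknown codes are rejected. Extra
#' regions can be appended from a YAML config (see [read_region_config()]),
#' which is also how a 21st label beyond the printed legend is supplied.
#'
#' @param extra optional data frame with columns `code` and `name` appended
#'   to the default registry.
#' @return data frame with columns `code`, `name` and class
#'   `"region_registry"`.
#' @examples
#' reg <- region_registry()
#' normalize_region("tha", reg)
#' @export
region_registry <- function(extra = NULL) {
  reg <- data.frame(
    code = c("SmG", "STG", "MTG", "ITG", "FG", "IFG", "SFG", "PFC", "Prec",
             "Ins", "Pari", "pACC", "mACC", "BG", "Hipp", "VC", "Tha",
             "SMC", "SMA", "Cere"),
    name = c("supramarginal gyrus", "superior temporal gyrus",
             "middle temporal gyrus", "inferior temporal gyrus",
             "frontal gyrus", "inferior frontal gyrus",
             "superior frontal gyrus", "prefrontal cortex",
             "pericalcarine cortex", "insula", "parietal lobe",
             "posterior cingulate cortex", "middle cingulate cortex",
             "basal ganglia", "hippocampus", "visual cortex", "thalamus",
             "primary motor sensory cortex", "supplementary motor area",
             "cerebellum"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), all(c("code", "name") %in% names(extra)))
    extra <- extra[!tolower(extra$code) %in% tolower(reg$code), , drop = FALSE]
    reg <- rbind(reg, extra[, c("code", "name")])
  }
  if (anyDuplicated(tolower(reg$code))) {
    stop_jmenet("duplicate region codes in registry")
  }
  class(reg) <- c("region_registry", "data.frame")
  reg
}

#' Resolve region codes against a registry
#'
#' Case-insensitive lookup returning the registry's canonical spelling.
#'
#' @param codes character vector of region codes.
#' @param registry a [region_registry()].
#' @return character vector of canonical codes.
#' @export
normalize_region <- function(codes, registry = region_registry()) {
  idx <- match(tolower(codes), tolower(registry$code))
  if (anyNA(idx)) {
    bad <- unique(codes[is.na(idx)])
    stop_jmenet("unknown region code(s): %s", paste(bad, collapse = ", "))
  }
  registry$code[idx]
}

#' Region-merging conventions
#'
#' The default merge map collapses anatomically and functionally close
#' labels onto one registry code: parietal lobule variants onto the parietal
#' lobe, the pre/postcentral gyri, posterior cingulate gyrus and SMA
#' anterior cluster onto the primary motor sensory cortex, thalamic
#' subregions onto the thalamus, and globus pallidus/putamen/caudate onto
#' the basal ganglia. Raw labels are matched case-insensitively.
#'
#' @return named character vector mapping raw label -> registry code.
#' @export
default_merge_map <- function() {
  c("parietal lobule"            = "Pari",
    "inferior parietal lobule"   = "Pari",
    "anterior central gyrus"     = "SMC",
    "posterior central gyrus"    = "SMC",
    "posterior cingulate gyrus"  = "SMC",
    "sma anterior cluster"       = "SMC",
    "thalamus subregion"         = "Tha",
    "globus pallidus"            = "BG",
    "putamen"                    = "BG",
    "caudate"                    = "BG",
    "caudate nucleus"            = "BG")
}

#' Read a region registry and merge map from YAML
#'
#' Expects a file with a `regions:` section (list of `code`/`name` entries
#' appended to the default registry) and a `merge:` section (map raw label
#' -> registry code).
#'
#' @param path YAML file path.
#' @return list with elements `registry` and `merge_map`.
#' @export
read_region_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  extra <- NULL
  if (length(cfg$regions)) {
    extra <- do.call(rbind, lapply(cfg$regions, function(r) {
      data.frame(code = r$code, name = r$name %||% r$code,
                 stringsAsFactors = FALSE)
    }))
  }
  registry <- region_registry(extra)
  merge_map <- character(0)
  if (length(cfg$merge)) {
    merge_map <- vapply(cfg$merge, as.character, character(1))
    names(merge_map) <- names(cfg$merge)
  }
  list(registry = registry, merge_map = merge_map)
}
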