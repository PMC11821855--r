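# Shared vocabulary and small helpers.

#' Controlled vocabularies
#'
#' Category levels used throughout the package: the nine neuron superclasses,
#' the neurotransmitter labels carried by FlyWire-style tables, the four
#' gustatory modalities, and the default subesophageal-zone (SEZ) neuropils.
#'
#' @return A character vector of category labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
taste_modalities <- function() c("sugar", "water", "bitter", "ir94e")

#' @rdname vocabularies
#' @export
neuron_superclasses <- function() {
  c("sensory", "ascending", "central", "descending", "motor",
    "endocrine", "visual_projection", "visual_centrifugal", "optic")
}

#' @rdname vocabularies
#' @export
nt_levels <- function() c("ACH", "GABA", "GLUT", "DA", "SER", "OCT", "unknown")

#' @rdname vocabularies
#' @export
sez_neuropils <- function() c("GNG", "PRW", "SAD", "FLA", "CAN")

# Normalize a vector of labels onto a controlled vocabulary; anything not in
# the vocabulary (case-insensitive) becomes `fallback`.
normalize_levels <- function(x, levels, fallback = "unknown") {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- fallback
  idx <- match(toupper(x), toupper(levels))
  out <- ifelse(is.na(idx), fallback, levels[ifelse(is.na(idx), 1L, idx)])
  out
}

# Split a neuropil code into base region and hemisphere ("L"/"R"/NA).
# Trailing "_L"/"_R" marks a lateralized region; anything else (including the
# SEZ neuropils) is non-lateralized. Missing/placeholder codes -> NA region.
parse_neuropil <- function(x) {
  x <- as.character(x)
  bad <- is.na(x) | !nzchar(x) | toupper(x) %in% c("NONE", "NA")
  hemi <- rep(NA_character_, length(x))
  base <- x
  is_l <- grepl("_L$", x)
  is_r <- grepl("_R$", x)
  hemi[is_l] <- "L"
  hemi[is_r] <- "R"
  base[is_l | is_r] <- sub("_[LR]$", "", x[is_l | is_r])
  base[bad] <- NA_character_
  hemi[bad] <- NA_character_
  tibble(region = base, hemi = hemi)
}

stop_tastetrace <- function(msg, class) {
  abort(msg, class = c(class, "tastetrace_error"))
}
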