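#' Build a drug-name synonym table
#'
#' Maps verbatim drug-name strings (brand names, salts, development codes such
#' as "LY3298176") to canonical ingredient names. Lookup is case- and
#' surrounding-whitespace-insensitive. User-supplied rows are merged over the
#' shipped defaults, which cover the eight GLP-1 receptor agonists and
#' metformin.
#'
#' @param extra optional data.frame with columns `verbatim`, `canonical`
#'   merged over (and overriding) the shipped defaults.
#' @return An object of class `synonym_table`: a named character vector keyed
#'   by upper-cased verbatim string.
#' @export
synonym_table <- function(extra = NULL) {
  path <- system.file("extdata", "drug_synonyms.csv", package = "faersdp",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    if (!all(c("verbatim", "canonical") %in% names(extra))) {
      stop("`extra` must have columns verbatim, canonical", call. = FALSE)
    }
    df <- rbind(extra[c("verbatim", "canonical")], df)
  }
  key <- toupper(trimws(df$verbatim))
  keep <- !duplicated(key)  # first wins, so extras override defaults
  map <- df$canonical[keep]
  names(map) <- key[keep]
  structure(map, class = "synonym_table")
}

#' Normalize verbatim drug names to canonical ingredients
#'
#' @param verbatim character vector of non-empty verbatim drug names.
#' @param table a [synonym_table].
#' @return data.frame with columns `verbatim`, `canonical` (the input string
#'   unchanged when unmatched) and logical `matched`.
#' @examples
#' tab <- synonym_table()
#' normalize_drug_name("LY3298176", tab)
#' @export
normalize_drug_name <- function(verbatim, table = synonym_table()) {
  stopifnot(inherits(table, "synonym_table"))
  if (!is.character(verbatim) || length(verbatim) == 0L) {
    stop("`verbatim` must be a character vector", call. = FALSE)
  }
  if (any(is.na(verbatim)) || any(!nzchar(trimws(verbatim)))) {
    stop("empty drug name", call. = FALSE)
  }
  key <- toupper(trimws(verbatim))
  hit <- unclass(table)[key]
  matched <- !is.na(hit)
  data.frame(verbatim = verbatim,
             canonical = ifelse(matched, hit, verbatim),
             matched = matched,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Drug class membership table
#'
#' Canonical ingredient names grouped into the classes the pipeline uses for
#' exposure cohorting (glp1ra, metformin) and unmasking exclusion lists
#' (psychotropic classes: benzodiazepines, antidepressants, antipsychotics,
#' opioids, sedatives, gabaergic; antidiabetic classes: sglt2i, dpp4i, tzd,
#' agi, sulfonylureas).
#'
#' @return data.frame with columns `class`, `drug` (lower-case canonical name).
#' @export
drug_classes <- function() {
  path <- system.file("extdata", "drug_classes.csv", package = "faersdp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default unmasking exclusion class lists
#'
#' @return Named list of two character vectors of class names: `psychotropic`
#'   (drugs that can themselves cause or treat the study events) and
#'   `antidiabetic` (concomitant glucose-lowering therapy other than the
#'   exposures of interest).
#' @export
default_unmasking_classes <- function() {
  list(
    psychotropic = c("benzodiazepines", "antidepressants", "antipsychotics",
                     "opioids", "sedatives", "gabaergic"),
    antidiabetic = c("sglt2i", "dpp4i", "tzd", "agi", "sulfonylureas")
  )
}

# class tag for a vector of canonical drug names (lower-cased); names not in
# the class table get "other"
drug_class_of <- function(canonical) {
  dc <- drug_classes()
  cls <- dc$class[match(tolower(canonical), dc$drug)]
  # cohorting only distinguishes glp1ra / metformin / everything else, but the
  # finer class is kept for unmasking
  ifelse(is.na(cls), "other", cls)
}
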