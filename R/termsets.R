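#' Construct a MedDRA preferred-term set
#'
#' A term set is a named collection of MedDRA preferred terms (PTs) standing
#' for a standardised MedDRA query (SMQ) concept. Matching against report
#' reactions is case-insensitive and whitespace-trimmed.
#'
#' @param name character scalar, e.g. `"suicide_self_injury"`.
#' @param preferred_terms character vector of PT strings (non-empty, unique
#'   after case folding).
#' @return An object of class `term_set`: a list with elements `name` and
#'   `preferred_terms` (stored lower-cased).
#' @examples
#' ts <- term_set("example", c("Depressed mood", "Anhedonia"))
#' ts$preferred_terms
#' @export
term_set <- function(name, preferred_terms) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(preferred_terms) || length(preferred_terms) == 0L) {
    stop("`preferred_terms` must be a non-empty character vector", call. = FALSE)
  }
  pts <- tolower(trimws(preferred_terms))
  if (anyDuplicated(pts)) {
    stop("duplicate preferred terms after case folding in term set '", name, "'",
         call. = FALSE)
  }
  structure(list(name = name, preferred_terms = pts), class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", x$name, ": ", length(x$preferred_terms), " preferred terms\n",
      sep = "")
  invisible(x)
}

#' Default SMQ term sets for depression and suicide/self-injury
#'
#' Ships the two narrow-scope SMQ PT lists used throughout the pipeline:
#' `depression_ex_suicide` (12 PTs, depression excluding suicide and
#' self-injury) and `suicide_self_injury` (9 PTs).
#'
#' @return Named list of [term_set] objects.
#' @export
default_term_sets <- function() {
  path <- system.file("extdata", "term_sets.csv", package = "faersdp",
                      mustWork = TRUE)
  read_term_sets(path)
}

#' Read term sets from a two-column CSV
#'
#' @param path CSV with columns `term_set`, `preferred_term`.
#' @return Named list of [term_set] objects, one per distinct `term_set` value.
#' @export
read_term_sets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("term_set", "preferred_term")
  if (!all(need %in% names(df))) {
    stop("term-set file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(split(df$preferred_term, df$term_set), function(terms) terms)
  out <- Map(term_set, names(sets), sets)
  names(out) <- names(sets)
  out
}
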