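#' FAERS-style relational report tables
#'
#' Container for one bundle of FAERS-style ASCII tables. All six tables are
#' data.frames keyed by `primaryid` (report ID) and `caseid` (case ID);
#' dates are 4-, 6- or 8-digit strings (year / year+month / full date).
#'
#' Expected columns:
#' * `demo`: primaryid, caseid, fda_dt (receipt date), event_dt, sex,
#'   age, age_cod, wt, wt_cod, occp_cod (report source)
#' * `drug`: primaryid, caseid, drug_seq, role_cod (PS/SS/C/I), drugname
#' * `reac`: primaryid, caseid, pt
#' * `ther`: primaryid, caseid, dsg_drug_seq, start_dt
#' * `outc`: primaryid, caseid, outc_cod
#' * `rpsr`: primaryid, caseid, rpsr_cod
#'
#' @param demo,drug,reac,ther,outc,rpsr data.frames as above.
#' @param quarter optional quarter label matching `YYYYQ[1-4]`.
#' @return An object of class `faers_tables` (a named list of the six
#'   data.frames with a `quarter` attribute).
#' @export
faers_tables <- function(demo, drug, reac, ther, outc, rpsr, quarter = NULL) {
  x <- structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                      outc = outc, rpsr = rpsr),
                 quarter = quarter, class = "faers_tables")
  validate_faers_tables(x)
  x
}

faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "wt", "wt_cod", "occp_cod"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  rpsr = c("primaryid", "caseid", "rpsr_cod")
)

validate_faers_tables <- function(x) {
  for (tab in names(faers_schema)) {
    df <- x[[tab]]
    if (!is.data.frame(df)) stop(tab, " must be a data.frame", call. = FALSE)
    missing <- setdiff(faers_schema[[tab]], names(df))
    if (length(missing)) {
      stop("table ", toupper(tab), " missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  known <- x$demo$primaryid
  for (tab in c("drug", "reac", "ther", "outc", "rpsr")) {
    orphan <- setdiff(x[[tab]]$primaryid, known)
    if (length(orphan)) {
      stop("table ", toupper(tab), " has primaryid(s) absent from DEMO: ",
           paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
    }
  }
  q <- attr(x, "quarter")
  if (!is.null(q) && !grepl("^[0-9]{4}Q[1-4]$", q)) {
    stop("quarter label must match YYYYQ[1-4], got '", q, "'", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.faers_tables <- function(x, ...) {
  q <- attr(x, "quarter")
  cat("<faers_tables>", if (!is.null(q)) paste0(" [", q, "]"), "\n", sep = "")
  for (tab in names(faers_schema)) {
    cat(sprintf("  %-4s %6d rows\n", toupper(tab), nrow(x[[tab]])))
  }
  invisible(x)
}

#' Parse FAERS date strings
#'
#' FAERS dates are 4-digit (year), 6-digit (year+month) or 8-digit (full)
#' strings. Only 8-digit dates yield a calendar `Date`; partial dates keep
#' the known components.
#'
#' @param x character (or numeric) vector of date strings; `""`/`NA` allowed.
#' @return data.frame with integer columns `year`, `month`, `day`, a `date`
#'   column (`Date`, `NA` unless precision is `"day"`) and `precision` in
#'   `{"day","month","year","missing"}`.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  n <- nchar(x)
  ok <- grepl("^[0-9]*$", x) & n %in% c(0L, 4L, 6L, 8L)
  precision <- rep("missing", length(x))
  precision[ok & n == 4L] <- "year"
  precision[ok & n == 6L] <- "month"
  precision[ok & n == 8L] <- "day"
  year <- ifelse(n >= 4L & ok, suppressWarnings(as.integer(substr(x, 1, 4))), NA_integer_)
  month <- ifelse(n >= 6L & ok, suppressWarnings(as.integer(substr(x, 5, 6))), NA_integer_)
  day <- ifelse(n == 8L & ok, suppressWarnings(as.integer(substr(x, 7, 8))), NA_integer_)
  date <- rep(as.Date(NA), length(x))
  full <- which(precision == "day")
  if (length(full)) {
    date[full] <- as.Date(x[full], format = "%Y%m%d")
    bad <- full[is.na(date[full])]
    precision[bad] <- "missing"  # e.g. 20230231
  }
  data.frame(year = year, month = month, day = day, date = date,
             precision = precision, stringsAsFactors = FALSE)
}

faers_file_names <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
                      ther = "THER.txt", outc = "OUTC.txt", rpsr = "RPSR.txt")

read_faers_ascii <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  ncol <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = ncol),
                        stringsAsFactors = FALSE)
    names(df) <- header
    return(df)
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a trailing empty field; pad rows ending in '$'
  lens <- lengths(parts) + endsWith(body, "$")
  bad <- which(lens != ncol)
  if (length(bad)) {
    stop("parse error in ", basename(path), " line ", bad[[1L]] + 1L,
         ": expected ", ncol, " fields, found ", lens[[bad[[1L]]]],
         call. = FALSE)
  }
  mat <- matrix("", nrow = length(parts), ncol = ncol)
  for (j in seq_len(ncol)) {
    mat[, j] <- vapply(parts, function(p) if (j <= length(p)) p[[j]] else "", "")
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Read one quarter of FAERS-style ASCII tables
#'
#' Reads the six '$'-delimited tables (first line is the '$'-separated
#' header) from a directory, validating field counts per row.
#'
#' @param dir directory containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `THER.txt`, `OUTC.txt`, `RPSR.txt`.
#' @param quarter optional quarter label (`YYYYQ[1-4]`); defaults to the
#'   directory basename when it matches that pattern.
#' @return A [faers_tables] bundle.
#' @export
read_quarter <- function(dir, quarter = NULL) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  if (is.null(quarter) && grepl("^[0-9]{4}Q[1-4]$", basename(dir))) {
    quarter <- basename(dir)
  }
  tabs <- lapply(faers_file_names, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
    read_faers_ascii(path)
  })
  faers_tables(tabs$demo, tabs$drug, tabs$reac, tabs$ther, tabs$outc,
               tabs$rpsr, quarter = quarter)
}

#' Write one quarter of FAERS-style ASCII tables
#'
#' Writes '$'-delimited files with a header line and one row per record.
#' The dialect has no quoting or escaping, so fields containing `'$'` are
#' rejected.
#'
#' @param tables a [faers_tables] bundle.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_quarter <- function(tables, dir) {
  validate_faers_tables(tables)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tab in names(faers_file_names)) {
    df <- tables[[tab]]
    df[] <- lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
    if (any(vapply(df, function(col) any(grepl("$", col, fixed = TRUE)), TRUE))) {
      stop("field containing the '$' delimiter in table ", toupper(tab),
           "; the FAERS ASCII dialect has no escaping", call. = FALSE)
    }
    path <- file.path(dir, faers_file_names[[tab]])
    lines <- c(paste(names(df), collapse = "$"),
               if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "$")))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Combine several quarterly bundles into one
#'
#' @param bundles list of [faers_tables].
#' @return A single [faers_tables] with the quarter attribute dropped.
#' @export
bind_quarters <- function(bundles) {
  stopifnot(length(bundles) >= 1L)
  tabs <- lapply(names(faers_schema), function(tab) {
    do.call(rbind, lapply(bundles, `[[`, tab))
  })
  names(tabs) <- names(faers_schema)
  faers_tables(tabs$demo, tabs$drug, tabs$reac, tabs$ther, tabs$outc, tabs$rpsr)
}

#' Deduplicate cases, keeping the most recent report
#'
#' FAERS cases are resubmitted as follow-ups under the same `caseid` with a
#' new `primaryid`; analyses keep one report per case. The rule is: keep the
#' report with the latest receipt date (`fda_dt`), ties broken by the largest
#' `primaryid`. All six tables are filtered to the surviving reports; output
#' order is stable by `caseid`.
#'
#' @param tables a [faers_tables] bundle.
#' @return A deduplicated [faers_tables].
#' @export
deduplicate <- function(tables) {
  validate_faers_tables(tables)
  demo <- tables$demo
  if (nrow(demo) == 0L) return(tables)
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  ord <- order(demo$caseid, demo$fda_dt, pid_num,
               method = "radix", decreasing = c(FALSE, TRUE, TRUE))
  demo <- demo[ord, , drop = FALSE]
  demo <- demo[!duplicated(demo$caseid), , drop = FALSE]
  demo <- demo[order(demo$caseid, method = "radix"), , drop = FALSE]
  keep <- demo$primaryid
  out <- tables
  out$demo <- demo
  for (tab in c("drug", "reac", "ther", "outc", "rpsr")) {
    df <- tables[[tab]]
    out[[tab]] <- df[df$primaryid %in% keep, , drop = FALSE]
  }
  rownames(out$demo) <- NULL
  validate_faers_tables(out)
  out
}

#' Normalize all drug names in a bundle
#'
#' Adds `canonical` and `class` columns to the DRUG table using a synonym
#' table and the shipped drug-class map.
#'
#' @param tables a [faers_tables] bundle.
#' @param synonyms a [synonym_table].
#' @return The bundle with an augmented DRUG table.
#' @export
normalize_drugs <- function(tables, synonyms = synonym_table()) {
  drug <- tables$drug
  if (nrow(drug)) {
    norm <- normalize_drug_name(drug$drugname, synonyms)
    drug$canonical <- tolower(norm$canonical)
    drug$class <- drug_class_of(drug$canonical)
  } else {
    drug$canonical <- character(0)
    drug$class <- character(0)
  }
  tables$drug <- drug
  tables
}
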