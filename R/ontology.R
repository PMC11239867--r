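## ICD-10 code handling, cohort table I/O, prevalence filtering and
## directional-pair enumeration.

#' Default ICD-10 chapter map
#'
#' Returns the chapter ranges used throughout the package: the 16 top-level
#' ICD-10 chapters covering body systems from infectious diseases (A00-B99)
#' through the special-purpose block (U00-U49). Ranges are non-overlapping and
#' every three-character category maps to at most one chapter.
#'
#' @param path Optional path to a CSV with columns `chapter`, `first`, `last`
#'   (and optionally `name`). Defaults to the map shipped with the package.
#' @return A data.frame with columns `chapter`, `first`, `last`, `name`.
#' @export
#' @examples
#' head(chapter_map())
chapter_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "icd10_chapters.csv", package = "morbidmap")
  }
  cm <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chapter", "first", "last") %in% names(cm)))
  if (is.null(cm$name)) cm$name <- cm$chapter
  bad <- cm$first > cm$last
  if (any(bad)) stop("chapter ranges must satisfy first <= last")
  o <- order(cm$first)
  cm <- cm[o, , drop = FALSE]
  if (nrow(cm) > 1 && any(cm$first[-1] <= cm$last[-nrow(cm)])) {
    stop("chapter ranges overlap")
  }
  rownames(cm) <- NULL
  cm
}

#' Truncate ICD-10 codes to three-character categories
#'
#' Diagnoses are analysed at the three-character category level (e.g. "I10",
#' "J44"); subcategory suffixes such as "I10.9" or "J449" are dropped.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector of three-character categories.
#' @export
truncate_icd3 <- function(code) {
  code <- toupper(gsub("[. ]", "", as.character(code)))
  out <- substr(code, 1L, 3L)
  ok <- grepl("^[A-Z][0-9]{2}$", out)
  if (any(!ok)) {
    stop("malformed ICD-10 code(s): ", paste(unique(code[!ok]), collapse = ", "))
  }
  out
}

#' Map an ICD-10 code to its chapter
#'
#' @param code Character vector of ICD-10 codes (three-character categories, or
#'   longer codes which are truncated first).
#' @param chapters Chapter map, as returned by [chapter_map()].
#' @return Character vector of chapter identifiers (e.g. `"I00-I99"`).
#'   Codes falling outside every chapter range raise an error naming them as
#'   outside the study chapters.
#' @export
#' @examples
#' map_chapter("I10")  # "I00-I99"
map_chapter <- function(code, chapters = chapter_map()) {
  code3 <- truncate_icd3(code)
  idx <- vapply(code3, function(cc) {
    hit <- which(chapters$first <= cc & cc <= chapters$last)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  if (anyNA(idx)) {
    stop("code(s) outside study chapters: ",
         paste(unique(code3[is.na(idx)]), collapse = ", "))
  }
  unname(chapters$chapter[idx])
}

#' Build a diagnosis table
#'
#' Long-format diagnosis records: one row per (participant, disease) with the
#' onset day relative to baseline (day 0). Negative or zero onset days mark
#' diagnoses prevalent at baseline; positive days are incident during
#' follow-up. At most one record per participant/disease is kept (the
#' earliest onset).
#'
#' @param id Participant identifiers.
#' @param code ICD-10 codes (truncated to three characters).
#' @param onset_day Integer days relative to baseline.
#' @param follow_up_end Scalar or per-record follow-up end day (> 0).
#' @param sex Cohort stratum label.
#' @return A `diagnosis_table`: data.frame `(id, code, onset_day)` with
#'   attributes `follow_up_end` (named vector per participant) and `sex`.
#' @export
diagnosis_table <- function(id, code, onset_day, follow_up_end, sex = "unspecified") {
  code <- truncate_icd3(code)
  onset_day <- as.integer(round(onset_day))
  df <- data.frame(id = as.character(id), code = code, onset_day = onset_day,
                   stringsAsFactors = FALSE)
  ## keep earliest onset per (participant, code)
  df <- df[order(df$id, df$code, df$onset_day), , drop = FALSE]
  df <- df[!duplicated(df[c("id", "code")]), , drop = FALSE]
  fu <- follow_up_end
  if (length(fu) == 1L) {
    ids <- unique(df$id)
    fu <- setNames(rep(as.numeric(fu), length(ids)), ids)
  } else {
    if (is.null(names(fu))) stop("per-participant follow_up_end must be named")
    fu <- fu[unique(df$id)]
  }
  if (any(df$onset_day > fu[df$id])) stop("onset after follow-up end")
  rownames(df) <- NULL
  structure(df, follow_up_end = fu, sex = sex, class = c("diagnosis_table", "data.frame"))
}

#' Per-sex prevalence filter
#'
#' Retains diseases whose prevalence (fraction of participants ever diagnosed,
#' at baseline or during follow-up) is strictly greater than `threshold`.
#'
#' @param diag A `diagnosis_table`.
#' @param cov Covariate table (one row per participant, column `id`); defines
#'   the denominator, so participants without any diagnosis still count.
#' @param threshold Prevalence threshold in (0, 1); default 0.01.
#' @param mode `"ever"` (default) counts baseline-prevalent plus incident
#'   diagnoses; `"baseline"` counts only diagnoses with onset day <= 0.
#' @return Character vector of retained disease codes, sorted.
#' @export
prevalence_filter <- function(diag, cov, threshold = 0.01, mode = c("ever", "baseline")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  n <- length(unique(cov$id))
  if (n == 0L) stop("empty cohort")
  d <- diag
  if (mode == "baseline") d <- d[d$onset_day <= 0, , drop = FALSE]
  carriers <- table(d$code[!duplicated(d[c("id", "code")])])
  keep <- names(carriers)[as.numeric(carriers) / n > threshold]
  sort(keep)
}

#' Enumerate ordered disease pairs
#'
#' All ordered pairs (a, b) with a != b, in deterministic lexicographic order
#' (by a, then b). For D diseases this yields D*(D-1) directional pairs; e.g.
#' 154 diseases give 23,562 pairs and 160 give 25,440.
#'
#' @param diseases Character vector of >= 2 disease codes.
#' @return data.frame with columns `a`, `b`.
#' @export
enumerate_pairs <- function(diseases) {
  diseases <- as.character(diseases)
  if (anyDuplicated(diseases)) stop("duplicate disease codes")
  D <- length(diseases)
  if (D < 2L) stop("need at least 2 diseases")
  ds <- sort(diseases)
  a <- rep(ds, each = D - 1L)
  b <- unlist(lapply(seq_len(D), function(i) ds[-i]), use.names = FALSE)
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Read / write cohort tables
#'
#' CSV exchange format for diagnosis and covariate tables. Diagnosis CSVs have
#' columns `id, code, onset_day, follow_up_end`; covariate CSVs have `id`,
#' `sex` and arbitrary further covariate columns. Writers emit UTF-8 with a
#' deterministic row order.
#'
#' @param diag,cov Tables to write.
#' @param path File path.
#' @param sex Stratum label used when reading a diagnosis table.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_diagnosis_table <- function(diag, path) {
  fu <- attr(diag, "follow_up_end")
  out <- data.frame(id = diag$id, code = diag$code, onset_day = diag$onset_day,
                    follow_up_end = as.numeric(fu[diag$id]))
  out <- out[order(out$id, out$code), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_diagnosis_table <- function(path, sex = "unspecified") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  fu <- tapply(df$follow_up_end, df$id, max)
  diagnosis_table(df$id, df$code, df$onset_day,
                  follow_up_end = setNames(as.numeric(fu), names(fu)), sex = sex)
}

#' @rdname cohort_io
#' @export
write_covariate_table <- function(cov, path) {
  cov <- cov[order(cov$id), , drop = FALSE]
  write.csv(cov, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_covariate_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
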