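#' Read a medical claims table
#'
#' Reads a delimited text file of patient visit records, one row per visit.
#' The file must have a header naming the five columns `patient_id`,
#' `visit_date`, `department_id`, `medicine_ids` and `label`. Dates are
#' ISO 8601 (`YYYY-MM-DD`). The `medicine_ids` cell holds zero or more
#' medicine tokens separated by `med_sep`; duplicates within a cell are
#' an error. Labels are `1` (fraud), `0` (non-fraud) or empty/NA
#' (unlabelled); a patient must carry at most one distinct label across
#' all its rows.
#'
#' @param path Path to a CSV or TSV file (delimiter auto-detected from the
#'   extension; `.tsv`/`.txt` read as tab, anything else as comma).
#' @param sep Field delimiter; overrides the extension-based default.
#' @param med_sep Separator between medicine tokens within one cell.
#' @return A `data.frame` of class `mhamfd_claims` with columns
#'   `patient_id` (character), `visit_date` (`Date`), `department_id`
#'   (character), `medicine_ids` (list of character vectors) and `label`
#'   (integer, `NA` = unlabelled). Row order follows the file.
#' @seealso [write_claims()], [build_hetero_graph()]
#' @export
read_claims <- function(path, sep = NULL, med_sep = ";") {
  if (!file.exists(path)) stop("claims file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, stringsAsFactors = FALSE)
  required <- c("patient_id", "visit_date", "department_id", "medicine_ids", "label")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("claims file is missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) return(new_claims(character(), as.Date(character()),
                                         character(), list(), integer()))

  pid <- trimws(raw$patient_id)
  dep <- trimws(raw$department_id)
  dat_raw <- trimws(raw$visit_date)
  # line number in file = data row + 1 (header)
  bad <- which(pid == "" | dep == "" | dat_raw == "")
  if (length(bad) > 0L)
    stop("empty patient_id/visit_date/department_id at line(s): ",
         paste(bad + 1L, collapse = ", "))

  ok_iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", dat_raw)
  dates <- as.Date(ifelse(ok_iso, dat_raw, NA), format = "%Y-%m-%d")
  bad <- which(!ok_iso | is.na(dates))
  if (length(bad) > 0L)
    stop("unparseable ISO 8601 date(s) at line(s): ",
         paste(sprintf("%d (%s)", bad + 1L, dat_raw[bad]), collapse = ", "))

  meds <- lapply(raw$medicine_ids, function(cell) {
    cell <- trimws(cell)
    if (is.na(cell) || cell == "") return(character())
    toks <- trimws(strsplit(cell, med_sep, fixed = TRUE)[[1L]])
    toks[toks != ""]
  })
  dup <- which(vapply(meds, anyDuplicated, 0L) > 0L)
  if (length(dup) > 0L)
    stop("duplicate medicine token within a visit at line(s): ",
         paste(dup + 1L, collapse = ", "))

  lab_raw <- trimws(raw$label)
  lab <- rep(NA_integer_, length(lab_raw))
  lab[lab_raw %in% "0"] <- 0L
  lab[lab_raw %in% "1"] <- 1L
  bad <- which(!(lab_raw %in% c("", "NA", "0", "1")))
  if (length(bad) > 0L)
    stop("label must be 0, 1 or empty; offending line(s): ",
         paste(bad + 1L, collapse = ", "))

  claims <- new_claims(pid, dates, dep, meds, lab)
  check_label_consistency(claims)
  claims
}

new_claims <- function(patient_id, visit_date, department_id, medicine_ids, label) {
  df <- data.frame(patient_id = as.character(patient_id),
                   visit_date = as.Date(visit_date),
                   department_id = as.character(department_id),
                   label = as.integer(label),
                   stringsAsFactors = FALSE)
  df$medicine_ids <- lapply(medicine_ids, as.character)
  df <- df[, c("patient_id", "visit_date", "department_id", "medicine_ids", "label")]
  class(df) <- c("mhamfd_claims", "data.frame")
  df
}

check_label_consistency <- function(claims) {
  lab <- split(claims$label, claims$patient_id)
  n_distinct <- vapply(lab, function(x) length(unique(x[!is.na(x)])), 0L)
  conflict <- names(n_distinct)[n_distinct > 1L]
  if (length(conflict) > 0L)
    stop("conflicting fraud labels for patient(s): ",
         paste(conflict, collapse = ", "))
  invisible(claims)
}

#' Write a claims table
#'
#' Inverse of [read_claims()]: writes one row per visit with medicines
#' joined by `med_sep` and unlabelled rows given an empty label cell, so
#' that reading the file back yields an identical record set.
#'
#' @param claims A claims table as returned by [read_claims()] or
#'   [simulate_claims()].
#' @param path Output file path (`.tsv`/`.txt` write tab-delimited,
#'   anything else comma-delimited).
#' @param med_sep Separator joining medicine tokens within a cell.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path, med_sep = ";") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- data.frame(
    patient_id = claims$patient_id,
    visit_date = format(claims$visit_date, "%Y-%m-%d"),
    department_id = claims$department_id,
    medicine_ids = vapply(claims$medicine_ids, paste, "", collapse = med_sep),
    label = ifelse(is.na(claims$label), "", as.character(claims$label)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-patient feature table
#'
#' Reads a delimited numeric feature table whose first column is
#' `patient_id`, and reindexes its rows to the supplied patient order.
#' Every patient must be present exactly once and every cell finite.
#'
#' @param path Path to a CSV/TSV file.
#' @param patients Character vector giving the required patient order.
#' @param sep Field delimiter; default by extension as in [read_claims()].
#' @return A numeric matrix with one row per element of `patients`
#'   (rownames set to the patient ids).
#' @export
read_features <- function(path, patients, sep = NULL) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1L] != "patient_id")
    stop("feature table must have 'patient_id' as its first column")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate patient_id in feature table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  absent <- setdiff(patients, ids)
  if (length(absent) > 0L)
    stop("patients present in claims but absent from feature table: ",
         paste(absent, collapse = ", "))
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L)
        stop(sprintf("non-numeric feature cell at row %d, column '%s'",
                     bad[1L], names(vals)[j]))
      v <- vn
    }
    if (any(!is.finite(v)))
      stop(sprintf("non-finite feature cell at row %d, column '%s'",
                   which(!is.finite(v))[1L], names(vals)[j]))
    vals[[j]] <- v
  }
  X <- as.matrix(vals)
  rownames(X) <- ids
  X <- X[match(patients, ids), , drop = FALSE]
  storage.mode(X) <- "double"
  X
}

#' Structural fallback features
#'
#' When no feature table accompanies the claims, each patient is described
#' by a z-scored structural summary of its own visit history: visit count,
#' number of distinct departments, distinct medicines, distinct visit
#' dates, and mean medicines per visit, padded with zero columns up to
#' `k`. These summaries describe single-patient behaviour only; they carry
#' no cross-patient co-visit information.
#'
#' @param claims A claims table.
#' @param k Output feature dimension (`k >= 5` pads, `k < 5` truncates).
#' @return A numeric matrix, one row per distinct patient (claims order of
#'   first appearance), `k` columns.
#' @export
structural_features <- function(claims, k = 8L) {
  patients <- unique(claims$patient_id)
  idx <- split(seq_len(nrow(claims)), factor(claims$patient_id, levels = patients))
  summ <- t(vapply(idx, function(i) {
    meds <- unlist(claims$medicine_ids[i])
    c(n_visits = length(i),
      n_departments = length(unique(claims$department_id[i])),
      n_medicines = length(unique(meds)),
      n_dates = length(unique(claims$visit_date[i])),
      mean_meds = length(meds) / length(i))
  }, numeric(5)))
  sds <- apply(summ, 2L, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  Z <- scale(summ, center = TRUE, scale = sds)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  X <- matrix(0, nrow(Z), k, dimnames = list(patients, paste0("f", seq_len(k))))
  take <- seq_len(min(k, ncol(Z)))
  X[, take] <- Z[, take]
  X
}

#' Write patient embeddings as TSV
#'
#' @param H Numeric matrix of final embeddings, rownames = patient ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(H, path) {
  out <- data.frame(patient_id = rownames(H), H, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("patient_id", paste0("e", seq_len(ncol(H))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
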