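#' Build the attributed heterogeneous information network
#'
#' Turns a claims table into a four-type heterogeneous graph with node
#' sets Patient (P), Time (T, calendar dates at day granularity),
#' Medicine (M) and Department (D). Every visit event contributes a
#' patient--department edge, a patient--date edge and one patient--medicine
#' edge per medicine in the visit, all tagged with the visit they came
#' from so that downstream conjunction relations can demand co-occurrence
#' within a single joint visit. Rows identical in patient, date,
#' department and medicine set are collapsed to one visit; repeat visits
#' that differ in any of these stay distinct.
#'
#' Only patient nodes carry features; the other node types are purely
#' structural.
#'
#' @param claims A claims table ([read_claims()] / [simulate_claims()]).
#' @param features Optional numeric matrix, one row per distinct patient
#'   in claims order of first appearance (rownames, if present, must match
#'   the patient ids). `NULL` falls back to [structural_features()].
#' @return An object of class `hetero_graph`: node vectors `patients`,
#'   `dates`, `medicines`, `departments`; a `visits` data.frame
#'   (`visit_id`, `patient_id`, `visit_date`, `department_id`) with a
#'   parallel `visit_medicines` list; per-patient `labels` (integer,
#'   `NA` = unlabelled); and the patient `features` matrix.
#' @export
build_hetero_graph <- function(claims, features = NULL) {
  if (nrow(claims) == 0L) stop("cannot build a graph from an empty claims table")
  check_label_consistency(claims)

  med_key <- vapply(claims$medicine_ids,
                    function(m) paste(sort(m), collapse = "\r"), "")
  key <- paste(claims$patient_id, format(claims$visit_date, "%Y-%m-%d"),
               claims$department_id, med_key, sep = "\n")
  keep <- !duplicated(key)

  patients <- unique(claims$patient_id)
  visits <- data.frame(
    visit_id = seq_len(sum(keep)),
    patient_id = claims$patient_id[keep],
    visit_date = format(claims$visit_date[keep], "%Y-%m-%d"),
    department_id = claims$department_id[keep],
    stringsAsFactors = FALSE)
  visit_medicines <- claims$medicine_ids[keep]

  lab_by_patient <- vapply(split(claims$label, factor(claims$patient_id, levels = patients)),
                           function(x) {
                             u <- unique(x[!is.na(x)])
                             if (length(u) == 0L) NA_integer_ else u
                           }, 0L)

  if (is.null(features)) {
    features <- structural_features(claims)
  } else {
    features <- as.matrix(features)
    if (nrow(features) != length(patients))
      stop("feature matrix has ", nrow(features), " rows but claims contain ",
           length(patients), " distinct patients")
    if (!is.null(rownames(features))) {
      if (!setequal(rownames(features), patients))
        stop("feature rownames do not match the claim patients")
      features <- features[patients, , drop = FALSE]
    } else {
      rownames(features) <- patients
    }
    if (any(!is.finite(features))) stop("feature matrix contains non-finite values")
  }

  g <- list(patients = patients,
            dates = sort(unique(visits$visit_date)),
            medicines = sort(unique(unlist(visit_medicines))),
            departments = sort(unique(visits$department_id)),
            visits = visits,
            visit_medicines = visit_medicines,
            labels = lab_by_patient,
            features = features)
  class(g) <- "hetero_graph"
  g
}

#' Summarise graph composition
#'
#' Computes the node count per type, the edge count per link type
#' (patient--department, patient--date, patient--medicine) and the
#' labelled/unlabelled patient counts of a heterogeneous claims graph.
#' Edge counts follow conservation: one P--D and one P--T edge per visit,
#' and one P--M edge per medicine per visit.
#'
#' @param g A `hetero_graph`.
#' @return A list of class `hetero_graph_summary` with elements `nodes`
#'   (named counts P, T, M, D), `edges` (named counts PD, PT, PM) and
#'   `labels` (named counts fraud, non_fraud, unlabelled).
#' @export
graph_summary <- function(g) {
  stopifnot(inherits(g, "hetero_graph"))
  nodes <- c(P = length(g$patients), T = length(g$dates),
             M = length(g$medicines), D = length(g$departments))
  nv <- nrow(g$visits)
  edges <- c(PD = nv, PT = nv,
             PM = sum(lengths(g$visit_medicines)))
  labels <- c(fraud = sum(g$labels == 1L, na.rm = TRUE),
              non_fraud = sum(g$labels == 0L, na.rm = TRUE),
              unlabelled = sum(is.na(g$labels)))
  structure(list(nodes = nodes, edges = edges, labels = labels),
            class = "hetero_graph_summary")
}

#' @export
print.hetero_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("Attributed heterogeneous claims graph\n")
  cat(sprintf("  nodes: P=%d T=%d M=%d D=%d  (visits: %d)\n",
              s$nodes["P"], s$nodes["T"], s$nodes["M"], s$nodes["D"],
              nrow(x$visits)))
  cat(sprintf("  edges: P-D=%d P-T=%d P-M=%d\n",
              s$edges["PD"], s$edges["PT"], s$edges["PM"]))
  cat(sprintf("  patients: %d fraud, %d non-fraud, %d unlabelled\n",
              s$labels["fraud"], s$labels["non_fraud"], s$labels["unlabelled"]))
  cat(sprintf("  features: %d x %d\n", nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' @export
print.hetero_graph_summary <- function(x, ...) {
  cat("nodes:  ", paste(names(x$nodes), x$nodes, sep = "=", collapse = "  "), "\n")
  cat("edges:  ", paste(names(x$edges), x$edges, sep = "=", collapse = "  "), "\n")
  cat("labels: ", paste(names(x$labels), x$labels, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Dump a heterogeneous graph as JSON
#'
#' Writes node lists and the typed, visit-tagged edge list for external
#' inspection. Not a round-trip format.
#'
#' @param g A `hetero_graph`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  edges <- rbind(
    data.frame(type = "PD", from = g$visits$patient_id,
               to = g$visits$department_id, visit = g$visits$visit_id),
    data.frame(type = "PT", from = g$visits$patient_id,
               to = g$visits$visit_date, visit = g$visits$visit_id),
    data.frame(type = "PM",
               from = rep(g$visits$patient_id, lengths(g$visit_medicines)),
               to = unlist(g$visit_medicines),
               visit = rep(g$visits$visit_id, lengths(g$visit_medicines))))
  jsonlite::write_json(
    list(nodes = list(P = g$patients, T = g$dates, M = g$medicines,
                      D = g$departments),
         edges = edges),
    path, auto_unbox = TRUE)
  invisible(path)
}
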