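#' Enumerate behavioural-relationship paths
#'
#' A behavioural relationship links two patients who share one joint
#' visit-pair agreeing on every entity type in the path: department (D),
#' date (T) and/or medicine (M). Its level is the number of shared entity
#' types. The seven valid paths are PDP, PTP, PMP (single level), PDTP,
#' PDMP, PTMP (dual level) and PDTMP (triple level), named with the
#' canonical entity order D before T before M.
#'
#' @param max_level Highest level to enumerate, in 1..3.
#' @return A list of `relation_path` objects, each with `name` (e.g.
#'   `"PDTP"`), `shared_types` (subset of `c("D","T","M")`) and `level`,
#'   ordered by level then canonically within level.
#' @export
enumerate_relation_paths <- function(max_level = 3L) {
  if (!is.numeric(max_level) || length(max_level) != 1L ||
      !(max_level %in% 1:3))
    stop("max_level must be 1, 2 or 3")
  types <- c("D", "T", "M")
  subsets <- list()
  for (lev in seq_len(max_level)) {
    combos <- utils::combn(types, lev, simplify = FALSE)
    # combn preserves the canonical D < T < M order within each subset
    subsets <- c(subsets, combos)
  }
  lapply(subsets, function(s) {
    structure(list(name = paste0("P", paste(s, collapse = ""), "P"),
                   shared_types = s, level = length(s)),
              class = "relation_path")
  })
}

#' @export
print.relation_path <- function(x, ...) {
  cat(sprintf("behavioural relationship %s (level %d: shares %s)\n",
              x$name, x$level, paste(x$shared_types, collapse = ", ")))
  invisible(x)
}

visit_join_key <- function(vt, shared_types) {
  parts <- list()
  if ("D" %in% shared_types) parts <- c(parts, list(vt$department_id))
  if ("T" %in% shared_types) parts <- c(parts, list(vt$visit_date))
  if ("M" %in% shared_types) parts <- c(parts, list(vt$medicine_id))
  do.call(paste, c(parts, sep = "\r"))
}

#' Patient--patient adjacency under one behavioural relationship
#'
#' Patients i and j (i != j) are neighbours under a path iff some visit of
#' i and some visit of j jointly satisfy all the path's conditions: same
#' department if D is shared, same date if T is shared, and intersecting
#' medicine sets if M is shared -- all on that one visit pair. Sharing a
#' department in one visit pair and a date in another does not qualify.
#' The adjacency is symmetric and irreflexive; the number of witnessing
#' visit pairs is retained per edge as a diagnostic multiplicity.
#'
#' @param g A `hetero_graph`.
#' @param path A `relation_path` from [enumerate_relation_paths()].
#' @return An object of class `relation_adjacency`: the `path`, the
#'   patient vector, `neighbors` (named list: for each patient, the
#'   character vector of its neighbours) and `pairs` (data.frame
#'   `patient_i`, `patient_j`, `multiplicity`, one row per ordered pair).
#' @export
build_relation_adjacency <- function(g, path) {
  stopifnot(inherits(g, "hetero_graph"), inherits(path, "relation_path"))
  vt <- g$visits[, c("visit_id", "patient_id", "visit_date", "department_id")]
  if ("M" %in% path$shared_types) {
    nmed <- lengths(g$visit_medicines)
    vt <- vt[rep(seq_len(nrow(vt)), nmed), , drop = FALSE]
    vt$medicine_id <- unlist(g$visit_medicines)
  }
  pairs <- if (nrow(vt) == 0L) {
    data.frame(patient_i = character(), patient_j = character(),
               multiplicity = integer(), stringsAsFactors = FALSE)
  } else {
    key <- visit_join_key(vt, path$shared_types)
    grp <- split(seq_len(nrow(vt)), key)
    grp <- grp[lengths(grp) > 1L]
    if (length(grp) == 0L) {
      data.frame(patient_i = character(), patient_j = character(),
                 multiplicity = integer(), stringsAsFactors = FALSE)
    } else {
      ii <- unlist(lapply(grp, function(ix) rep(ix, each = length(ix))),
                   use.names = FALSE)
      jj <- unlist(lapply(grp, function(ix) rep(ix, times = length(ix))),
                   use.names = FALSE)
      ok <- vt$patient_id[ii] != vt$patient_id[jj]
      ii <- ii[ok]; jj <- jj[ok]
      # one witness = one distinct ordered visit pair (a pair sharing two
      # medicines counts once)
      vp <- paste(vt$visit_id[ii], vt$visit_id[jj])
      keep <- !duplicated(vp)
      pi <- vt$patient_id[ii[keep]]
      pj <- vt$patient_id[jj[keep]]
      agg <- table(paste(pi, pj, sep = "\r"))
      nm <- strsplit(names(agg), "\r", fixed = TRUE)
      data.frame(patient_i = vapply(nm, `[`, "", 1L),
                 patient_j = vapply(nm, `[`, "", 2L),
                 multiplicity = as.integer(agg),
                 stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  neighbors <- lapply(stats::setNames(g$patients, g$patients),
                      function(p) character())
  if (nrow(pairs) > 0L) {
    nb <- split(pairs$patient_j, factor(pairs$patient_i, levels = g$patients))
    neighbors <- lapply(nb, function(x) sort(unique(x)))
  }
  structure(list(path = path, patients = g$patients,
                 neighbors = neighbors, pairs = pairs),
            class = "relation_adjacency")
}

#' All behavioural-relationship adjacencies of a graph
#'
#' @param g A `hetero_graph`.
#' @param max_level Highest relationship level to include (1..3).
#' @return A named list of `relation_adjacency` objects, one per path
#'   from [enumerate_relation_paths()], names = path names.
#' @export
build_all_relation_graphs <- function(g, max_level = 3L) {
  paths <- enumerate_relation_paths(max_level)
  adjs <- lapply(paths, function(p) build_relation_adjacency(g, p))
  names(adjs) <- vapply(paths, `[[`, "", "name")
  adjs
}

#' Dense logical adjacency matrix of a relation
#'
#' @param adj A `relation_adjacency`.
#' @return A symmetric logical matrix (patients x patients), diagonal
#'   `FALSE`.
#' @export
adjacency_matrix <- function(adj) {
  n <- length(adj$patients)
  A <- matrix(FALSE, n, n, dimnames = list(adj$patients, adj$patients))
  if (nrow(adj$pairs) > 0L) {
    A[cbind(match(adj$pairs$patient_i, adj$patients),
            match(adj$pairs$patient_j, adj$patients))] <- TRUE
  }
  A
}

#' Export a relation adjacency as an edge-list TSV
#'
#' @param adj A `relation_adjacency`.
#' @param path Output path. Columns: patient_id, patient_id, path,
#'   multiplicity; one row per ordered neighbour pair.
#' @return `path`, invisibly.
#' @export
write_adjacency_tsv <- function(adj, path) {
  out <- data.frame(patient_i = adj$pairs$patient_i,
                    patient_j = adj$pairs$patient_j,
                    path = adj$path$name,
                    multiplicity = adj$pairs$multiplicity,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Randomly cap neighbour counts
#'
#' Down-samples every neighbour set larger than `max_neighbors` uniformly
#' at random (seeded). Symmetry is restored afterwards by keeping an edge
#' if either endpoint kept it. Unlimited by default; intended only for
#' inputs too large for full attention.
#'
#' @param adj A `relation_adjacency`.
#' @param max_neighbors Cap per patient (`Inf` = no cap).
#' @param seed Integer seed for the down-sampling.
#' @return A `relation_adjacency` with capped neighbour sets (pairs table
#'   restricted accordingly; multiplicities preserved on kept edges).
#' @export
cap_neighbors <- function(adj, max_neighbors = Inf, seed = 1L) {
  if (!is.finite(max_neighbors)) return(adj)
  stopifnot(max_neighbors >= 1)
  set.seed(as.integer(seed))
  kept <- lapply(adj$neighbors, function(nb) {
    if (length(nb) <= max_neighbors) nb else sort(sample(nb, max_neighbors))
  })
  keep_edge <- function(i, j) j %in% kept[[i]] || i %in% kept[[j]]
  if (nrow(adj$pairs) > 0L) {
    ok <- mapply(keep_edge, adj$pairs$patient_i, adj$pairs$patient_j)
    adj$pairs <- adj$pairs[ok, , drop = FALSE]
  }
  nb <- split(adj$pairs$patient_j, factor(adj$pairs$patient_i, levels = adj$patients))
  adj$neighbors <- lapply(nb, function(x) sort(unique(x)))
  adj
}
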