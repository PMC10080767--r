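#' Simulate a claim population with planted fraud rings
#'
#' Generates synthetic visit records that emulate the structure of
#' municipal health-insurance claim data: four entity universes
#' (patients, calendar dates, medicines, departments) and fraud that
#' clusters structurally rather than attributively. Fraudulent patients
#' are partitioned into rings; every ring receives `co_visits_per_ring`
#' joint visit events whose shared entities depend on `signal_level`:
#' level 1 shares only the date (departments drawn independently per
#' member), level 2 shares department and date, and level 3 additionally
#' shares the medicine set. Every patient -- fraudulent or not -- also
#' receives `background_visits_per_patient` visits with uniformly random
#' department, date and medicines, which makes the single-level relation
#' graphs (same department or same date anywhere) dense and weakly
#' informative while conjunction relations stay sparse and enriched in
#' ring pairs.
#'
#' Default universe sizes scale the composition of a one-year municipal
#' claims extract (hundreds of departments and thousands of medicines for
#' thousands of patients) down to a 300-patient population with the
#' balanced 1:2 fraud ratio; a rare-fraud regime (about 1:70) is obtained
#' by lowering `n_fraud` relative to `n_normal`.
#'
#' @param n_fraud,n_normal Patient counts per class.
#' @param n_departments,n_dates,n_medicines Entity universe sizes (dates
#'   are consecutive days of 2018).
#' @param ring_size Fraud patients per ring (last ring may be smaller).
#' @param co_visits_per_ring Joint visit events per ring.
#' @param background_visits_per_patient Random visits per patient.
#' @param medicines_per_visit Medicines drawn per visit.
#' @param signal_level Which entity types ring co-visits share (1, 2
#'   or 3; see above).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list: `claims` (an `mhamfd_claims` table with every row
#'   labelled), `labels` (named integer vector per patient) and `rings`
#'   (list of fraud-patient id vectors).
#' @export
simulate_claims <- function(n_fraud = 100L, n_normal = 200L,
                            n_departments = 50L, n_dates = 351L,
                            n_medicines = 160L, ring_size = 5L,
                            co_visits_per_ring = 3L,
                            background_visits_per_patient = 4L,
                            medicines_per_visit = 3L,
                            signal_level = 2L, seed = 1L) {
  stopifnot(n_fraud >= 1, n_normal >= 1, n_departments >= 1, n_dates >= 1,
            n_medicines >= 1, ring_size >= 1, ring_size <= n_fraud,
            co_visits_per_ring >= 1, background_visits_per_patient >= 1,
            medicines_per_visit >= 1, signal_level %in% 1:3)
  if (medicines_per_visit > n_medicines)
    stop("medicine universe too small: cannot draw ", medicines_per_visit,
         " distinct medicines from ", n_medicines)
  set.seed(as.integer(seed))
  n <- n_fraud + n_normal
  patients <- sprintf("p%04d", seq_len(n))
  labels <- stats::setNames(c(rep(1L, n_fraud), rep(0L, n_normal)), patients)
  departments <- sprintf("d%03d", seq_len(n_departments))
  dates <- as.Date("2018-01-01") + seq_len(n_dates) - 1L
  medicines <- sprintf("m%04d", seq_len(n_medicines))

  rings <- split(patients[seq_len(n_fraud)],
                 ceiling(seq_len(n_fraud) / ring_size))
  rings <- unname(rings)

  pid <- character(); vdate <- as.Date(character())
  dep <- character(); meds <- list()

  draw_meds <- function() sort(sample(medicines, medicines_per_visit))
  for (ring in rings) {
    for (v in seq_len(co_visits_per_ring)) {
      t_shared <- sample(dates, 1L)
      d_shared <- sample(departments, 1L)
      m_shared <- draw_meds()
      for (p in ring) {
        pid <- c(pid, p)
        vdate <- c(vdate, t_shared)
        dep <- c(dep, if (signal_level >= 2L) d_shared else sample(departments, 1L))
        meds <- c(meds, list(if (signal_level >= 3L) m_shared else draw_meds()))
      }
    }
  }
  nb <- n * background_visits_per_patient
  pid <- c(pid, rep(patients, each = background_visits_per_patient))
  vdate <- c(vdate, sample(dates, nb, replace = TRUE))
  dep <- c(dep, sample(departments, nb, replace = TRUE))
  meds <- c(meds, replicate(nb, draw_meds(), simplify = FALSE))

  claims <- new_claims(pid, vdate, dep, meds, labels[pid])
  list(claims = claims, labels = labels, rings = rings)
}

#' Simulate per-patient attribute features
#'
#' Draws each patient's feature vector from a standard normal
#' distribution, shifting every coordinate of fraudulent patients by
#' `shift`. With `shift = 0` the features carry no label information at
#' all, which isolates the structural (co-visit) signal; a positive
#' shift gives an easy attribute signal for sanity runs.
#'
#' @param labels Named integer label vector (from [simulate_claims()]).
#' @param k Feature dimension.
#' @param shift Per-class mean shift added to fraud rows.
#' @param seed Integer seed.
#' @return A numeric matrix (patients x k), rownames = patient ids.
#' @export
simulate_features <- function(labels, k = 8L, shift = 0, seed = 1L) {
  stopifnot(k >= 1, shift >= 0)
  set.seed(as.integer(seed))
  n <- length(labels)
  X <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(names(labels), paste0("f", seq_len(k))))
  X[labels == 1L, ] <- X[labels == 1L, , drop = FALSE] + shift
  X
}
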