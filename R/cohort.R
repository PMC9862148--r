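#' Construct a discordant-twin family cohort
#'
#' The study design this package supports is a five-member nuclear family:
#' two parents, a pair of dizygotic twins discordant for specific reading
#' disability (SRD; exactly one twin affected), and an affected older sibling.
#' Genetic analyses use all five members; imaging analyses use the three
#' siblings.
#'
#' @param subjects A data frame with columns `subject_id`, `role` (one of
#'   `"parent"`, `"twin"`, `"older_sibling"`) and `affected` (logical).
#'   Defaults to the canonical cohort with ids `mother`, `father`, `proband`
#'   (affected twin), `td_twin` (unaffected twin), `older_sib` (affected).
#' @return A `family_cohort` object: the subject table plus
#'   `affected_sibling_ids` (affected twin first, then older sibling) and
#'   `discordant_id` (the unaffected twin).
#' @examples
#' coh <- family_cohort()
#' coh$discordant_id
#' @export
family_cohort <- function(subjects = NULL) {
  if (is.null(subjects)) {
    subjects <- tibble::tibble(
      subject_id = c("mother", "father", "proband", "td_twin", "older_sib"),
      role       = c("parent", "parent", "twin", "twin", "older_sibling"),
      affected   = c(FALSE, FALSE, TRUE, FALSE, TRUE)
    )
  }
  subjects <- tibble::as_tibble(subjects)
  req <- c("subject_id", "role", "affected")
  if (!all(req %in% names(subjects))) {
    ts_abort("cohort subjects need columns subject_id, role, affected",
             "cohort_error")
  }
  if (nrow(subjects) != 5L || anyDuplicated(subjects$subject_id)) {
    ts_abort("cohort must contain exactly 5 uniquely-identified subjects",
             "cohort_error")
  }
  if (!all(subjects$role %in% c("parent", "twin", "older_sibling"))) {
    ts_abort("roles must be parent, twin or older_sibling", "cohort_error")
  }
  n_role <- table(factor(subjects$role,
                         levels = c("parent", "twin", "older_sibling")))
  if (!identical(as.integer(n_role), c(2L, 2L, 1L))) {
    ts_abort("cohort must have 2 parents, 2 twins and 1 older sibling",
             "cohort_error")
  }
  twins <- subjects[subjects$role == "twin", ]
  older <- subjects[subjects$role == "older_sibling", ]
  if (sum(twins$affected) != 1L) {
    ts_abort("exactly one twin must be affected (discordant pair)",
             "cohort_error")
  }
  if (!older$affected) {
    ts_abort("the older sibling must be affected", "cohort_error")
  }
  if (any(subjects$affected[subjects$role == "parent"])) {
    ts_abort("parents must be unaffected in this design", "cohort_error")
  }
  structure(
    list(
      subjects = subjects,
      affected_sibling_ids = c(twins$subject_id[twins$affected],
                               older$subject_id),
      discordant_id = twins$subject_id[!twins$affected]
    ),
    class = "family_cohort"
  )
}

#' @export
print.family_cohort <- function(x, ...) {
  cat("<family_cohort> 5 subjects\n")
  cat("  affected siblings:", paste(x$affected_sibling_ids, collapse = ", "),
      "\n  discordant (unaffected) twin:", x$discordant_id, "\n")
  invisible(x)
}

#' Ids of the three imaged siblings
#'
#' Twins first (affected twin, then unaffected twin), then the older sibling.
#' @param cohort A [family_cohort()].
#' @return Character vector of length 3.
#' @export
sibling_ids <- function(cohort) {
  stopifnot(inherits(cohort, "family_cohort"))
  c(cohort$affected_sibling_ids[1], cohort$discordant_id,
    cohort$affected_sibling_ids[2])
}

#' Enumerate the three labeled sibling pairs
#'
#' A three-sibling cohort yields exactly three unordered pairs, the unit of
#' every pairwise comparison in the pipeline: `twin-twin` (the dizygotic
#' twins; the within-pair baseline), `SRD` (the two affected siblings) and
#' `TD-OS` (unaffected twin vs affected older sibling). The result is
#' invariant to the order in which subjects were supplied.
#'
#' @param cohort A [family_cohort()].
#' @return A tibble with columns `label`, `id1`, `id2`.
#' @export
enumerate_subject_pairs <- function(cohort) {
  stopifnot(inherits(cohort, "family_cohort"))
  sibs <- sibling_ids(cohort)
  if (length(unique(sibs)) != 3L) {
    ts_abort("expected exactly 3 imaged siblings", "cohort_error")
  }
  aff <- cohort$affected_sibling_ids
  td <- cohort$discordant_id
  tibble::tibble(
    label = c("twin-twin", "SRD", "TD-OS"),
    id1 = c(aff[1], aff[1], td),
    id2 = c(td, aff[2], aff[2])
  )
}
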