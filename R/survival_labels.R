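#' Binarize survival at the 5-year cut-off
#'
#' Patients who succumb to MIBC at or before the cut-off are labelled
#' bad prognosis; patients observed beyond the cut-off (whatever happens
#' later) are good prognosis; patients censored before the cut-off --
#' other-cause death or alive at last follow-up -- have an unknowable
#' 5-year status and are excluded.
#'
#' @param records data frame with `survival_months` (> 0) and
#'   `event_cause` in `c("mibc_death", "other_death", "alive_censored")`.
#' @param cutoff cut-off in months (default 60).
#' @return list with `labels` (character: "bad"/"good"/"excluded"),
#'   `reason` (character, non-empty for exclusions) and `report`
#'   (counts per label plus excluded fraction).
#' @export
binarize_survival <- function(records, cutoff = 60) {
  t <- records$survival_months
  cause <- records$event_cause
  if (any(!is.finite(t)) || any(t <= 0)) stop("survival_months must be positive")
  ok <- cause %in% c("mibc_death", "other_death", "alive_censored")
  if (!all(ok)) stop("unknown event_cause: ", paste(unique(cause[!ok]), collapse = ", "))
  labels <- rep("good", length(t))
  labels[cause == "mibc_death" & t <= cutoff] <- "bad"
  labels[cause != "mibc_death" & t < cutoff] <- "excluded"
  reason <- rep("", length(t))
  reason[labels == "excluded"] <- paste0("censored before cutoff (",
                                         cause[labels == "excluded"], ")")
  n <- length(labels)
  list(labels = labels, reason = reason,
       report = list(n = n,
                     n_bad = sum(labels == "bad"),
                     n_good = sum(labels == "good"),
                     n_excluded = sum(labels == "excluded"),
                     excluded_fraction = sum(labels == "excluded") / n))
}

.round_half_up <- function(x) floor(x + 0.5)

#' Stratified sample of indices
#'
#' Samples without replacement within each class so that class
#' proportions are preserved.  The total equals round-half-up of
#' `fraction * n`; per-class quotas start at the floor of
#' `fraction * class size` and the remaining units go to the classes
#' with the largest fractional remainders (ties to the larger class).
#' This reproduces both 75/25 at 20% giving 15 + 5, and 78 patients at
#' 25% giving a 20-patient sample.
#'
#' @param labels class label per subject.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return integer vector of selected indices (sorted).
#' @export
stratified_sample <- function(labels, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("every class must have at least one member")
  classes <- unique(labels)
  sizes <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(sizes < 1)) stop("every class must have at least one member")
  n <- length(labels)
  total <- .round_half_up(fraction * n)
  raw <- fraction * sizes
  quota <- floor(raw)
  rem <- raw - quota
  left <- total - sum(quota)
  if (left > 0) {
    ord <- order(-rem, -sizes, seq_along(classes))
    quota[ord[seq_len(left)]] <- quota[ord[seq_len(left)]] + 1
  } else if (left < 0) {
    ord <- order(rem, sizes, seq_along(classes))
    take <- ord[quota[ord] > 0][seq_len(-left)]
    quota[take] <- quota[take] - 1
  }
  set.seed(seed)
  picked <- unlist(lapply(seq_along(classes), function(k) {
    idx <- which(labels == classes[k])
    if (quota[k] == 0) integer(0) else sample(idx, quota[k])
  }))
  sort(as.integer(picked))
}

#' Stratified train/test split
#'
#' Test set drawn by [stratified_sample()] at `test_fraction`; the train
#' set is the complement.  Disjoint and exhaustive by construction.
#'
#' @inheritParams stratified_sample
#' @param test_fraction fraction held out (default 0.25, so a 78-patient
#'   cohort yields a 58/20 split).
#' @return list with integer `train` and `test` index vectors.
#' @export
stratified_split <- function(labels, test_fraction = 0.25, seed = 1L) {
  test <- stratified_sample(labels, test_fraction, seed = seed)
  list(train = setdiff(seq_along(labels), test), test = test)
}
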