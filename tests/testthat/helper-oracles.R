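# Independent oracles and small fixture builders shared across tests.

# hand-rolled product-limit estimator
km_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.integer(events)[ord]
  ut <- unique(times)
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# risk-table log-rank statistic for two groups (no ties assumption needed)
logrank_oracle <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- c(rep(1, length(t1)), rep(2, length(t2)))
  ut <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in ut) {
    n <- sum(times >= tt); n1 <- sum(times >= tt & grp == 1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & grp == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Breslow log partial likelihood for a single binary covariate
cox_pl_oracle <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force AUROC by pair counting
auc_oracle <- function(scores, labels, positive = "bad") {
  sp <- scores[labels == positive]; sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# cells on a spaced grid with fixed marker flags, for IF round-trips
grid_cells <- function(extent = 128, spacing = 16, seed = 1) {
  set.seed(seed)
  pos <- seq(spacing / 2, extent - spacing / 2, by = spacing)
  g <- expand.grid(x_um = pos, y_um = pos)
  markers <- c("CD3", "CD8", "CD68", "CD163", "PDL1", "PanCK")
  for (m in markers) g[[m]] <- sample(c(TRUE, FALSE), nrow(g), replace = TRUE)
  # every channel needs at least one positive for min-max normalisation
  for (m in markers) if (!any(g[[m]])) g[[m]][sample(nrow(g), 1)] <- TRUE
  g
}

# one small shared cohort, generated once per test session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_patients = 16, seed = 42)
      cache <<- list(cfg = cfg, cohort = generate_cohort(cfg))
    }
    cache
  }
})

# stub submodel: a function mapping a feature data frame to fixed votes
stub_vote <- function(prediction) {
  force(prediction)
  function(features) rep(prediction, nrow(features))
}
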