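## Independent oracles and small fixture builders shared across tests.

## Tie-free log partial likelihood, written directly from the definition:
## sum over events of eta_i - log(sum of exp(eta_j) over the risk set).
## Deliberately independent of the package's fitting code.
pl_loglik <- function(beta, x, time, event) {
  eta <- beta * x
  s <- 0
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    s <- s + eta[i] - log(sum(exp(eta[rs])))
  }
  s
}

## Brute-force maximizer of the log partial likelihood over a 1e-3 grid.
grid_cox <- function(x, time, event, grid = seq(-5, 5, by = 1e-3)) {
  ll <- vapply(grid, pl_loglik, numeric(1), x = x, time = time,
               event = event)
  grid[which.max(ll)]
}

## Mann-Whitney AUC of marker for cases (TRUE) vs controls (FALSE).
mw_auc <- function(marker, case) {
  mc <- marker[case]; mn <- marker[!case]
  cmp <- outer(mc, mn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Wrap a plain 0/1 matrix as a CodedMatrix (no homozygosity structure).
as_coded <- function(X) {
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  new("CodedMatrix", values = X, carrierFreq = colMeans(X == 1, na.rm = TRUE),
      parentVariable = setNames(rep(NA_character_, ncol(X)), colnames(X)),
      dropped = character(0), threshold = NA_real_)
}

## Simulate a simple cohort: binary markers with given carrier frequencies
## and log-hazard effects, exponential baseline, uniform censoring.
sim_simple <- function(n, freqs, betas, base = 0.05, cens = NULL,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(freqs)
  X <- sapply(freqs, function(f) rbinom(n, 1, f))
  colnames(X) <- sprintf("m%02d", seq_len(p))
  rownames(X) <- paste0("S", seq_len(n))
  eta <- as.numeric(X %*% betas)
  tm <- rexp(n, base * exp(eta))
  if (is.null(cens)) {
    ev <- rep(1L, n)
  } else {
    cs <- runif(n, 0, cens)
    ev <- as.integer(tm <= cs)
    tm <- pmin(tm, cs)
  }
  list(X = X, surv = survivalData(tm, ev))
}

## Reduced locus panels for runtime-bounded simulation tests.
small_panel <- function(which = c("C", "CT60")) {
  defaultLocusPanel()[which]
}

## The five planted marker names of the planted_five_marker scenario.
planted_markers <- c("B*38", "C*15", "C*03", "DRB1*15", "CT60*G/G")
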