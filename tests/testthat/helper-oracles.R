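# Independent brute-force oracles. These are deliberately written as plain
# loops over the definitions, so they share no code path with the package.

oracle_cindex <- function(risk, time, event) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (event[i] == 1 && time[i] < time[j]) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

oracle_cumulative_auc <- function(risk, time, event) {
  num <- 0
  den <- 0
  for (t in sort(unique(time[event == 1]))) {
    for (i in seq_along(risk)) {
      if (!(time[i] < t && event[i] == 1)) next
      for (j in seq_along(risk)) {
        if (!(time[j] > t)) next
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

oracle_cox_loss <- function(risk, time, event) {
  total <- 0
  for (i in seq_along(risk)) {
    if (event[i] != 1) next
    denom <- 0
    for (j in seq_along(risk)) {
      if (time[j] >= time[i]) denom <- denom + exp(risk[j])
    }
    total <- total + log(denom) - risk[i]
  }
  total
}

oracle_breslow <- function(risk, time, event) {
  ts <- sort(unique(time[event == 1]))
  ch <- numeric(length(ts))
  acc <- 0
  for (k in seq_along(ts)) {
    d <- sum(event == 1 & time == ts[k])
    denom <- sum(exp(risk[time >= ts[k]]))
    acc <- acc + d / denom
    ch[k] <- acc
  }
  list(time = ts, cumhaz = ch)
}

# Dense factorized-bilinear oracle: materializes each l x l slice U_j V_j^T.
oracle_fbm <- function(z1, z2, U, V) {
  m <- dim(U)[3]
  out <- matrix(0, nrow(z1), m)
  for (j in seq_len(m)) {
    B <- U[, , j] %*% t(V[, , j])
    for (i in seq_len(nrow(z1))) {
      out[i, j] <- drop(t(z1[i, ]) %*% B %*% z2[i, ])
    }
  }
  out
}

# Random right-censored cohort with ties in both times and risks.
rand_cohort <- function(n, seed) {
  set.seed(seed)
  list(risk = round(rnorm(n), 1),
       time = sample(seq_len(max(3, n %/% 2)), n, replace = TRUE),
       event = rbinom(n, 1, 0.6))
}

# Small simulated dataset for fast training tests.
small_sim <- function(seed = 1, n = 80, ...) {
  simulateCohort(simConfig(nSamples = n, pGene = 30, pMirna = 12,
                           betaAdditive = 2, betaCross = 1,
                           targetCensoring = 0.4, seed = seed, ...))
}
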