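# Independent brute-force oracles used to check the package's statistics.
# These deliberately take a different computational route from the
# implementation: t via stats::t.test, Mann-Whitney via full enumeration of
# group assignments, Fisher via dhyper enumeration over all tables with the
# observed margins, BH via a literal step-up loop, and the log-rank O/E/V
# via an explicit risk-set walk.

oracle_t <- function(a, b, pooled = TRUE) {
    fit <- stats::t.test(a, b, var.equal = pooled)
    list(t = unname(fit$statistic), p = fit$p.value,
         df = unname(fit$parameter))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into groups of sizes n1/n2 (no ties assumed).
oracle_mwu_exact <- function(a, b) {
    n1 <- length(a)
    n2 <- length(b)
    pool <- c(a, b)
    uStat <- function(idx) {
        x <- pool[idx]
        y <- pool[-idx]
        sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    }
    obs <- uStat(seq_len(n1))
    null <- apply(utils::combn(n1 + n2, n1), 2L, uStat)
    pLow <- mean(null <= obs)
    pHigh <- mean(null >= obs)
    list(u = obs, p = min(1, 2 * min(pLow, pHigh)))
}

# Two-sided Fisher p by summing hypergeometric probabilities of all tables
# with the observed margins whose probability does not exceed the observed
# table's (relative tie tolerance 1e-7).
oracle_fisher <- function(a, b, c, d) {
    m <- a + c      # first-column margin
    n <- b + d
    k <- a + b      # first-row margin
    support <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

oracle_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    running <- Inf
    for (i in rev(seq_len(m))) {
        running <- min(running, p[ord[i]] * m / i)
        adj[ord[i]] <- min(1, running)
    }
    adj
}

# Log-rank O/E/V for the "high" group by walking risk sets at each distinct
# event time, plus the one-step HR.
oracle_logrank <- function(time, event, high) {
    times <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (tj in times) {
        atRisk <- time >= tj
        nj <- sum(atRisk)
        n1j <- sum(atRisk & high)
        dj <- sum(time == tj & event == 1)
        d1j <- sum(time == tj & event == 1 & high)
        O <- O + d1j
        E <- E + dj * n1j / nj
        if (nj > 1)
            V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
    chi2 <- (O - E)^2 / V
    list(O = O, E = E, V = V, chi2 = chi2, hr = exp((O - E) / V))
}

# Small labelled score matrix with optional NAs, for io/screen fixtures.
make_score_matrix <- function(nLines = 6, nGenes = 4, seed = 1,
                              naFrac = 0) {
    set.seed(seed)
    m <- matrix(rnorm(nLines * nGenes), nLines, nGenes,
                dimnames = list(sprintf("ACH-%06d", seq_len(nLines)),
                                sprintf("GENE%d (%d)", seq_len(nGenes),
                                        seq_len(nGenes))))
    if (naFrac > 0) {
        idx <- sample(length(m), ceiling(naFrac * length(m)))
        m[idx] <- NA
    }
    m
}
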