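## Independent oracles and small fixture builders used across the suite.
## Oracles deliberately take a different computational route from the
## package implementation they check.

## Mann-Whitney oracle: U counted as pairwise wins + half-ties (not via
## rank sums), tail probabilities by enumerating group-label assignments.
mwLabelOracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  Ustat <- function(xi) {
    xs <- pooled[xi]
    ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  Uobs <- Ustat(seq_len(nx))
  Us <- apply(combn(n, nx), 2, Ustat)
  pl <- mean(Us <= Uobs + 1e-9)
  ph <- mean(Us >= Uobs - 1e-9)
  list(U = Uobs, p = min(1, 2 * min(pl, ph)))
}

## REML oracle: log-likelihood of the error contrasts A'y (A an
## orthonormal basis of the null space of X'), evaluated on a brute-force
## zoomed grid over (sigma_b^2, sigma_e^2).
remlContrastLik <- function(y, X, subject, sb2, se2) {
  qX <- qr(X)
  A <- qr.Q(qX, complete = TRUE)[, (qX$rank + 1):length(y), drop = FALSE]
  Z <- outer(subject, sort(unique(subject)), "==") * 1
  V <- se2 * diag(length(y)) + sb2 * tcrossprod(Z)
  S <- crossprod(A, V %*% A)
  yt <- crossprod(A, y)
  as.numeric(-0.5 * (determinant(S)$modulus +
                       crossprod(yt, solve(S, yt)) + nrow(S) * log(2 * pi)))
}

remlGridOracle <- function(y, X, subject, rounds = 3, width = 61) {
  vy <- var(y)
  lo <- c(1e-8 * vy, 1e-4 * vy)
  hi <- c(4 * vy, 4 * vy)
  best <- NULL
  for (r in seq_len(rounds)) {
    sb2s <- seq(lo[1], hi[1], length.out = width)
    se2s <- seq(lo[2], hi[2], length.out = width)
    ll <- outer(sb2s, se2s, Vectorize(function(a, b)
      remlContrastLik(y, X, subject, a, b)))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(sb2 = sb2s[idx[1]], se2 = se2s[idx[2]], ll = max(ll))
    stepB <- sb2s[2] - sb2s[1]
    stepE <- se2s[2] - se2s[1]
    lo <- c(max(0, best[1] - stepB), max(1e-8 * vy, best[2] - stepE))
    hi <- c(best[1] + stepB, best[2] + stepE)
  }
  best
}

## fixture builders ---------------------------------------------------------

makeCytoDF <- function(n = 3, group = rep("control", n)) {
  data.frame(subject_id = sprintf("s%d", seq_len(n)), group = group,
             cycle_id = sprintf("cyc%d", seq_len(n)),
             collection_day = rep(c("day0", "day1_2"), length.out = n),
             collection_time = rep(c("evening", "overnight"), length.out = n),
             CD45pos = 1000, CD66b_pos = 600, CD66b_neg = 400,
             Mono = 100, Tcell = 150, Bcell = 30, uNK = 50,
             CD45neg = 20, Epith = 5, Endo = 3, DoubleNeg = 10, SFC = 4,
             stringsAsFactors = FALSE)
}

makeDecidDF <- function(nPerGroup = 2, treatments = "cAMP", times = 6,
                        value = 10) {
  g <- expand.grid(
    subject_id = c(sprintf("c%d", seq_len(nPerGroup)),
                   sprintf("e%d", seq_len(nPerGroup))),
    treatment = treatments, time_h = times,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$group <- ifelse(grepl("^c", g$subject_id), "control", "endometriosis")
  g$igfbp1 <- value
  g
}

quietScreen <- function(...) suppressMessages(runPopulationScreen(...))
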