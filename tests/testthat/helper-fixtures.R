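## Shared fixture builders. Everything is generated in code; the only state
## kept across tests is a per-session cache of expensive cohorts.

.fix <- new.env(parent = emptyenv())

strataNames <- c("African", "Asian", "Caucasian", "LatinAmerican")

groupSizesMatrix <- function(ns, wbs = ns) {
  m <- rbind(NS = rep(ns, length.out = 4), WBS = rep(wbs, length.out = 4))
  colnames(m) <- strataNames
  m
}

## geometry-only cohort config: no texture stamps
geomOnlyConfig <- function(groupSizes, effects = NULL, modulation = NULL,
                           seed = 1L, ...) {
  SyntheticCohortConfig(
    groupSizes = groupSizes,
    geometricEffects = effects,
    textureEffects = data.frame(landmark = character(),
                                pattern = character(),
                                contrast = numeric()),
    stratumModulation = modulation, seed = seed, ...)
}

## a frozen deterministic configuration (no randomness at all)
frozenConfig <- function(groupSizes, ...) {
  geomOnlyConfig(groupSizes, landmarkJitterSD = 0, rotationRange = 0,
                 scaleRange = c(1, 1), translationRange = 0,
                 intensityNoiseSD = 0, ...)
}

featureMatrixOf <- function(fset) t(SummarizedExperiment::assay(fset, "features"))
diagnosisOf <- function(fset) as.character(SummarizedExperiment::colData(fset)$diagnosis)

## random similarity transform of a coordinate matrix
applySimilarity <- function(pts, theta, s, tx, ty) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(s * pts %*% t(R), 2, c(tx, ty), "+")
}

## Mann-Whitney enumeration oracle: exact two-sided p over all assignments
mwuOracle <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals); na <- length(a)
  r <- rank(vals)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  pl <- mean(us <= uObs + 1e-9); pu <- mean(us >= uObs - 1e-9)
  min(1, 2 * min(pl, pu))
}

## Fisher two-sided enumeration oracle (sum of hypergeometric probabilities
## <= that of the observed table, at the observed margins)
fisherOracle <- function(ca, ta, cb, tb) {
  K <- ca + cb
  xs <- max(0, K - tb):min(K, ta)
  pr <- stats::dhyper(xs, ta, tb, K)
  pObs <- stats::dhyper(ca, ta, tb, K)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}
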