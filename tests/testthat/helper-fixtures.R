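# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A small 3-subject study for unit tests.
smallStudy <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulateStudy(studyConfig(n_subjects = 3, seed = 11))
  .fixtures$small
}

# The default 9-subject study plus its preprocessed form (used by the
# end-to-end checks).
defaultStudy <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- simulateStudy(studyConfig(seed = 20))
  .fixtures$default
}

defaultPreprocessed <- function() {
  if (is.null(.fixtures$defaultPP))
    .fixtures$defaultPP <- preprocessSpectra(defaultStudy())
  .fixtures$defaultPP
}

# Balanced-accuracy-optimized PLS-DA dimension for BC vs HI on the
# default study (the tuning rule the pipeline prescribes).
optimizedA <- function() {
  if (is.null(.fixtures$Aopt)) {
    prob <- phaseProblem(defaultPreprocessed()$set, c("BC", "HI"))
    .fixtures$Aopt <- selectComponents(prob$X, prob$y, prob$subjects,
                                       A_range = 2:8)$A
  }
  .fixtures$Aopt
}

# Extract a samples x features design for a phase problem.
phaseProblem <- function(set, phases_wanted) {
  keep <- as.character(phases(set)) %in% phases_wanted
  list(X = t(intensities(set)[, keep, drop = FALSE]),
       y = as.character(phases(set))[keep],
       subjects = subjects(set)[keep])
}

# A toy RamanSpectraSet with known contents.
toySet <- function(n = 6, wn = seq(535, 1715, by = 4), seed = 1) {
  set.seed(seed)
  RamanSpectraSet(matrix(rnorm(length(wn) * n), ncol = n), wn,
                  data.frame(sample_id = paste0("s", seq_len(n)),
                             subject_id = rep(c("A", "B"),
                                              length.out = n),
                             phase = rep(c("BC", "HI"), length.out = n),
                             time_min = seq_len(n)))
}

# Two/three well-separated Gaussian clouds for classifier tests.
gaussClouds <- function(n_per = 40, centers = list(c(-5, 0), c(5, 0)),
                        sd = 1, seed = 1, subjects_per_class = 4) {
  set.seed(seed)
  X <- NULL; y <- character(); subj <- character()
  for (i in seq_along(centers)) {
    Xi <- cbind(rnorm(n_per, centers[[i]][1], sd),
                rnorm(n_per, centers[[i]][2], sd))
    X <- rbind(X, Xi)
    y <- c(y, rep(LETTERS[i], n_per))
    subj <- c(subj, rep(sprintf("S%d", ((seq_len(n_per) - 1) %%
                                          subjects_per_class) + 1),
                        each = 1))
  }
  list(X = X, y = y, subjects = subj)
}

# Brute-force AUROC by pair counting (ties = 1/2).
aurocBrute <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Brute-force rank-biserial as |concordant - discordant| pair fraction.
rankBiserialBrute <- function(x, y) {
  conc <- disc <- 0
  for (a in x) for (b in y) {
    conc <- conc + (a > b); disc <- disc + (a < b)
  }
  abs(conc - disc) / (length(x) * length(y))
}

# Exact Mann-Whitney p by enumerating all group assignments of the
# pooled sample (two-sided, by U as extreme or more extreme).
mwExactBrute <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  uStat <- function(idx) {
    r <- rank(pooled)
    u1 <- sum(r[idx]) - n1 * (n1 + 1) / 2
    min(u1, n1 * length(y) - u1)
  }
  obs <- uStat(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, uStat)
  mean(us <= obs)
}
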