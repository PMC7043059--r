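# Small programmatic fixtures shared across test files.

# A clean (no missing values) labeled synthetic dataset.
cleanDataset <- function(n = 120, p = 40, k = 3, ipc = 2, effect = 3,
                         seed = 1) {
  generateDataset(syntheticSpec(n, p, nClasses = k,
                                informativePerClass = ipc,
                                effectSize = effect, nanRate = 0,
                                seed = seed))
}

# Tiny hand-built DescriptorSet from an explicit matrix.
handDataset <- function(values, labels = NULL, vocabulary = NULL) {
  DescriptorSet(values, labels = labels, vocabulary = vocabulary)
}

# Four classes jointly coded by two binary-ish features: feature g1
# separates {a,b} from {c,d}, feature g2 separates {a,c} from {b,d}.
# Both features are needed for perfect classification.
jointCodedDataset <- function(nPerClass = 20, pNoise = 8, seed = 1) {
  set.seed(seed)
  classes <- c("a", "b", "c", "d")
  y <- rep(classes, each = nPerClass)
  n <- length(y)
  g1 <- ifelse(y %in% c("a", "b"), 0, 5) + rnorm(n, 0, 0.3)
  g2 <- ifelse(y %in% c("a", "c"), 0, 5) + rnorm(n, 0, 0.3)
  X <- cbind(g1 = g1, g2 = g2,
             matrix(rnorm(n * pNoise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(pNoise)))))
  rownames(X) <- sprintf("CID%04d", seq_len(n))
  DescriptorSet(X, labels = y)
}

# Independent kappa oracle: direct margin arithmetic, no shared code path.
kappaOracle <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- 0
  for (i in seq_len(nrow(cm)))
    pe <- pe + sum(cm[i, ]) * sum(cm[, i]) / n^2
  (po - pe) / (1 - pe)
}

# Closed-form 2x2 chi-square oracle: n(ad - bc)^2 / product of margins.
chi2Oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}
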