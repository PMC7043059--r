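#' @importFrom methods new validObject is slot show setValidity
#' @importFrom stats rnorm runif cor sd pchisq hclust dist as.dendrogram
#'   order.dendrogram quantile predict
#' @importFrom utils head tail
NULL

# Derive a reproducible sub-seed for a named stage from one master seed.
# Keeps results < 2^31 so set.seed() always accepts them.
deriveSeed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage))) %% 10007L
  as.integer((as.double(master) * 2654435.0 + h * 97.0 + index) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Majority vote over a molecules x trees matrix of integer class indices.
# Ties break to the lowest vocabulary index, so prediction is deterministic.
majorityVote <- function(votes, nClasses) {
  apply(votes, 1L, function(v) {
    tab <- tabulate(v, nbins = nClasses)
    which.max(tab)
  })
}

validFraction <- function(x) is.numeric(x) && length(x) == 1L &&
  !is.na(x) && x >= 0 && x <= 1

validCount <- function(x, min = 1L) is.numeric(x) && length(x) == 1L &&
  !is.na(x) && x == floor(x) && x >= min
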