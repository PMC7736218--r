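## Shared numerics and small IO helpers.

#' Draw ex-Gaussian variates
#'
#' Sum of a normal and an independent exponential component; the standard
#' positively skewed response-latency model.
#'
#' @param n number of draws.
#' @param mu,sigma normal component mean and SD.
#' @param tau exponential component mean.
#' @return numeric vector of draws.
#' @export
rexGauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, 1 / tau)
}

## Derive a child seed from a base seed, stream id and index, staying well
## below 2^31 so set.seed() always receives a valid 32-bit integer.
childSeed <- function(seed, stream, index = 0L) {
  as.integer((as.numeric(seed) * 1009 + stream * 97 + index) %% 2147483629)
}

#' Write a data.frame as TSV
#'
#' Tab-separated, no quoting, no row names; the on-disk format of all trial,
#' event and summary tables.
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{writeTsv}
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

## Nearest sample index for a time (ms) on an epoch time axis.
timeToIndex <- function(times, t) which.min(abs(times - t))

## Index range for a closed window [a, b] on a time axis (ms).
windowIndex <- function(times, win) {
  idx <- which(times >= win[1] & times <= win[2])
  if (!length(idx))
    stop("window [", win[1], ", ", win[2], "] ms lies outside the epoch")
  idx
}
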