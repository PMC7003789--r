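#' Derive a reproducible substream seed
#'
#' Maps a base seed and a (dataset, stream) index pair to a new integer seed
#' via a fixed multiplicative hash, so that every dataset and every model fit
#' in a simulation study has its own documented, collision-resistant RNG
#' substream. All arithmetic is exact in doubles and the result stays below
#' 2^31 - 1.
#'
#' @param base_seed integer base seed of the run.
#' @param index non-negative integer, e.g. the dataset replicate number.
#' @param stream non-negative integer distinguishing uses of the same index
#'   (e.g. one stream per fitted model).
#' @return a single integer seed.
#' @examples
#' substream_seed(1, 7)
#' substream_seed(1, 7, stream = 2)
#' @export
substream_seed <- function(base_seed, index, stream = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(base_seed) +
          as.numeric(index) * 48271 +
          as.numeric(stream) * 16807) %% m
  # one multiplicative scramble step (Lehmer); keeps 0 out of the range
  as.integer((x * 69621) %% m + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("nmashrink_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

all_pairs <- function(treatments) {
  if (length(treatments) < 2) {
    return(data.frame(t1 = character(), t2 = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- combn(length(treatments), 2)
  data.frame(t1 = treatments[idx[1, ]], t2 = treatments[idx[2, ]],
             stringsAsFactors = FALSE)
}
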