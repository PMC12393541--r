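#' @importFrom stats median quantile rnorm rpois rgamma rnbinom runif sd
#'   p.adjust wilcox.test t.test cor cor.test qt setNames complete.cases
#' @importFrom utils head tail
#' @importFrom rlang hash abort warn inform %||%
NULL

# interval helpers: all internal coordinates are 0-based half-open [start, end)

interval_width <- function(iv) {
  if (is.null(iv) || length(iv) == 0) return(0L)
  sum(iv[, 2] - iv[, 1])
}

# reduce a 2-column interval matrix to its disjoint union
interval_union <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(iv)
  ir <- IRanges::reduce(IRanges::IRanges(start = iv[, 1] + 1L, end = iv[, 2]))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# vector of 1-based base indices covered by 0-based half-open intervals
interval_bases <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(iv)), function(i) seq.int(iv[i, 1] + 1L, iv[i, 2])),
         use.names = FALSE)
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

other_strand <- function(strand) ifelse(strand == "+", "-", "+")

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, n) x[sample.int(length(x), n)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
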