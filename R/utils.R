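#' Fork a reproducible sub-seed from a master seed
#'
#' Derives a deterministic 32-bit sub-seed from a master seed and a text
#' label. Each sub-generator (stations, mortality, factors, fold splits,
#' annealing moves, ...) seeds its own stream with a labelled fork, so
#' enlarging one component (e.g. adding stations) never perturbs the draws
#' of another.
#'
#' @param seed Integer master seed.
#' @param label Character label naming the stream.
#' @return An integer in `[0, 2^31)`, suitable for [set.seed()].
#' @export
#' @examples
#' fork_seed(1L, "stations")
fork_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  h <- 17
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tm <- function(fmt, ..., class) {
  stop(structure(class = c(class, "tempmort_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Percentile with the linear-interpolation convention
#'
#' Thin wrapper around [stats::quantile()] type 7 (linear interpolation
#' between order statistics), the convention used for the cold/heat
#' reference thresholds. Exposed so callers can substitute another type.
#'
#' @param x Numeric vector.
#' @param p Percentile in `[0, 100]`.
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Scalar percentile value.
#' @keywords internal
percentile <- function(x, p, type = 7) {
  unname(stats::quantile(x, probs = p / 100, type = type, names = FALSE,
                         na.rm = FALSE))
}

# ISO day sequence starting at `start`, length n
date_seq <- function(start, n) as.Date(start) + seq_len(n) - 1L

# check dates form a contiguous daily sequence; returns missing dates
date_gaps <- function(dates) {
  d <- as.Date(dates)
  full <- seq(min(d), max(d), by = "day")
  full[!full %in% d]
}
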