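#' @keywords internal
"_PACKAGE"

## Run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG stream afterwards. All stochastic entry points funnel through
## this so that determinism contracts hold regardless of ambient RNG use.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic derivation of per-stage seeds from a root seed; keeps every
## derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Mean count per visit from printed totals
#'
#' The per-visit mean used throughout cohort summaries: a total event count
#' divided by the number of visits. Exposed because descriptive tables in this
#' field report totals alongside the derived means.
#'
#' @param total total number of events (e.g. diagnosis codes assigned across
#'   all visits).
#' @param n_visits number of visits.
#' @return `total / n_visits` as a numeric scalar.
#' @examples
#' per_visit_mean(109625, 28728)
#' @export
per_visit_mean <- function(total, n_visits) {
  stopifnot(is.numeric(total), is.numeric(n_visits), n_visits > 0)
  as.numeric(total) / as.numeric(n_visits)
}

## Numerically safe logistic; preserves dim attributes.
sigmoid <- function(z) {
  p <- z
  pos <- z >= 0
  p[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  p[!pos] <- ez / (1 + ez)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
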