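#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded internals never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a component sub-seed from a global seed
#'
#' One global integer seed drives independent per-component generators: each
#' component hashes its name (and any extra keys) into a distinct stream so
#' that, e.g., adding reference signatures never changes the count matrix.
#' Result is always in `[1, 2^31 - 20)`.
#'
#' @param seed global integer seed.
#' @param ... character/numeric keys identifying the component.
#' @return integer seed.
#' @keywords internal
sub_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483591
  as.integer((abs(as.numeric(seed)) %% 2147483591 + h * 7919 + 1) %% 2147483591 + 1)
}

## stop() with a classed condition so callers can distinguish configuration
## errors from runtime failures
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("proxscreen_config_error", "error")))
}

stop_sim <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("proxscreen_sim_error", "error")))
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x == round(x)

## Benjamini-Hochberg, kept as a named wrapper so strata code reads clearly
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
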