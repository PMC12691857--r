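# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG state
#'
#' Seeds the RNG with `seed`, evaluates `code`, and restores the caller's
#' RNG state afterwards, so generators are pure functions of their spec.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Clean an edge table: trim ids, enforce positive weights, optionally
# canonicalize unordered pairs (a <= b lexically), collapse duplicates
# keeping the maximum weight. Returns a data.frame(from, to, weight).
clean_edges <- function(edges, weighted, canonicalize, drop_loops, context) {
  if (is.null(edges) || nrow(edges) == 0) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  if (ncol(edges) < 2) stopf("%s: edge table needs at least 2 columns", context)
  from <- trimws(as.character(edges[[1]]))
  to <- trimws(as.character(edges[[2]]))
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stopf("%s: empty node identifier in edge table", context)
  }
  if (weighted) {
    if (ncol(edges) < 3) stopf("%s: weighted but no weight column", context)
    weight <- as.numeric(edges[[3]])
    if (any(!is.finite(weight)) || any(weight <= 0)) {
      stopf("%s: edge weights must be positive finite numbers", context)
    }
  } else {
    weight <- rep(1, length(from))
  }
  if (drop_loops) {
    loops <- from == to
    if (any(loops)) {
      warnf("%s: dropped %d self-loop(s)", context, sum(loops))
      from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
    }
  }
  if (canonicalize) {
    lo <- pmin(from, to)
    hi <- pmax(from, to)
    from <- lo; to <- hi
  }
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    wmax <- tapply(weight, key, max)
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
    weight <- as.numeric(wmax[key[keep]])
    message(sprintf("%s: collapsed %d duplicate edge record(s), keeping the maximum weight",
                    context, ndup))
  }
  data.frame(from = from, to = to, weight = weight, stringsAsFactors = FALSE)
}
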