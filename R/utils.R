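# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded routines do not
#' perturb the global RNG stream.  `seed = NULL` leaves the stream alone.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic arithmetic on the stage name so pipeline stages can be rerun
#' in isolation with the seed the full run would have used.  Result is kept
#' inside the 32-bit integer range `set.seed()` accepts.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(master_seed) %% 2147483647 + h * 7919) %% 2147483647)
}

# id hygiene: identifiers are case-sensitive but whitespace-trimmed
trim_ids <- function(x) {
  x <- trimws(as.character(x))
  if (anyDuplicated(x)) {
    stop("duplicate identifiers after whitespace trimming: ",
         paste(unique(x[duplicated(x)]), collapse = ", "))
  }
  if (any(x == "")) stop("empty identifier")
  x
}

# canonical unordered pair key, lexicographic, used for deterministic tie-breaks
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
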