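#' @keywords internal
"_PACKAGE"

## Input checking helpers --------------------------------------------------

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x),
          "`%s` must be a single finite number", name)
  stop_if(x < lower || x > upper, "`%s` must be in [%g, %g], got %g",
          name, lower, upper, x)
  stop_if(!allow_zero && x == 0, "`%s` must be non-zero", name)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x),
          "`%s` must be a single integer", name)
  stop_if(x < lower, "`%s` must be >= %d", name, lower)
  invisible(as.integer(x))
}

## Seeded evaluation: restores the caller's RNG state afterwards, so that
## generators are deterministic without clobbering the session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## Well naming for row-major multiwell plates: A1..A6, B1..B6, ...
#' Standard well names for a multiwell plate
#'
#' Wells are named row-major (`A1`, `A2`, ..., `B1`, ...) with 6 columns for
#' a 24-well plate, 12 for 96 wells, and otherwise the closest to a square
#' layout.
#'
#' @param n_wells Number of wells.
#' @return Character vector of `n_wells` unique well ids.
#' @export
well_names <- function(n_wells) {
  n_wells <- check_count(n_wells, "n_wells", lower = 1L)
  n_cols <- if (n_wells %% 6 == 0 && n_wells <= 48) 6L
            else if (n_wells %% 12 == 0) 12L
            else ceiling(sqrt(n_wells))
  n_rows <- ceiling(n_wells / n_cols)
  ids <- as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)))
  ids[seq_len(n_wells)]
}
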