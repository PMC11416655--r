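# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

ft_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Fractional-rank normalization to the unit interval
#'
#' Maps a numeric vector to \[0, 1\] via average-tie fractional ranks, so the
#' column minimum maps to 0 and the maximum to 1. Constant vectors map to 0.5.
#' Missing values stay missing.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length in \[0, 1\].
#' @export
rank_unit <- function(x) {
  r <- rank(x, ties.method = "average", na.last = "keep")
  rng <- range(r, na.rm = TRUE)
  if (!is.finite(rng[1]))
    return(rep(NA_real_, length(x)))
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (r - rng[1]) / (rng[2] - rng[1])
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  invisible(ids)
}

# Derive `n` child seeds from one master seed without clobbering the caller's
# RNG state. Streams are positional: stream k is stable no matter how many
# streams are requested afterwards.
derive_seeds <- function(master_seed, n, salt = 0L) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(master_seed) + as.integer(salt)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

ft_log <- function(..., level = "info") {
  lv <- getOption("ferrotarget.log_level", "info")
  order <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (order[[level]] >= order[[lv %||% "info"]] && lv != "quiet")
    message(sprintf("[%s] %s", level, sprintf(...)))
  invisible(NULL)
}
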