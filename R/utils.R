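# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded simulation
#' functions do not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-electrode substream seed. Electrode substreams depend
# only on (top seed, electrode index), so appending electrodes never
# perturbs the draws of existing ones. Kept strictly below 2^31.
substream_seed <- function(seed, idx) {
  ((seed %% 100003L) * 20011 + idx * 7919 + 104729) %% 2147483647
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition pairs per task: reference condition first ("now"/"here"); the
# reference is the normalization condition for the modulation features.
task_conditions <- function(task) {
  switch(task,
    time  = c("now", "then"),
    space = c("here", "there"),
    stop_input("unknown task label: ", task)
  )
}

# Labels an epoch set may carry before condition collapsing.
allowed_conditions <- function(task) {
  switch(task,
    time  = c("now", "then", "past", "future"),
    space = c("here", "there"),
    stop_input("unknown task label: ", task)
  )
}
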