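# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a deterministic child seed from a master seed and labels
#'
#' Reproducibility across a factorial study design without seed bookkeeping
#' by the caller: each (participant, scene, session, trial) combination gets
#' its own RNG stream derived by a polynomial string hash of the labels,
#' folded into the master seed modulo 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the child stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "waveform", "P01", "scene3")
child_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1; h * 31 + byte stays well below 2^53
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    for (b in utf8ToInt(paste0("|", paste(as.character(part), collapse = ",")))) {
      h <- (h * 31 + b) %% m
    }
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_numeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
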