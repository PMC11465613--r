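# internal helpers shared across modules

# quantile function of N(mean, sd) truncated to [lower, upper]
qtnorm <- function(p, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + p * (pu - pl), mean, sd)
}

# random draw from a truncated normal (inversion; respects the active RNG stream)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  qtnorm(runif(n), mean, sd, lower, upper)
}

# coerce a yes/no/NA character (or logical) column to logical
yn_to_lgl <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[x %in% c("yes", "TRUE", "true", "1")] <- TRUE
  out[x %in% c("no", "FALSE", "false", "0")] <- FALSE
  out
}

lgl_to_yn <- function(x) ifelse(is.na(x), NA_character_, ifelse(x, "yes", "no"))

# coerce labels to logical case indicator, validating content
as_case <- function(labels, arg = "labels") {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- yn_to_lgl(labels)
  y <- as.logical(labels)
  if (anyNA(y)) abort(sprintf("`%s` contains missing values.", arg))
  y
}

check_probs <- function(probs, arg = "probs", open = FALSE) {
  if (!is.numeric(probs) || anyNA(probs)) {
    abort(sprintf("`%s` must be numeric with no missing values.", arg))
  }
  bad <- if (open) any(probs <= 0 | probs >= 1) else any(probs < 0 | probs > 1)
  if (bad) {
    abort(sprintf(
      "`%s` must lie %s.", arg,
      if (open) "strictly inside (0, 1)" else "in [0, 1]"
    ))
  }
  invisible(probs)
}

`%||%` <- rlang::`%||%`
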